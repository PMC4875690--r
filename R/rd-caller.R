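#' GC-bias correction of a binned depth track
#'
#' Bins are grouped into integer-percent GC classes; each bin's depth is
#' rescaled by the ratio of the global mean depth to its GC class mean,
#' which removes the unimodal GC-coverage dependence. Classes with fewer
#' than `min_bins` bins are too small for a stable class mean and fall back
#' to no correction. When no class falls back, the genome-wide mean depth is
#' preserved exactly.
#'
#' @param track a `depth_track`.
#' @param layout the `genome_layout` providing per-bin GC.
#' @param min_bins minimum bins per GC class for correction (default 100).
#' @return the track with `corrected_depth` filled in.
#' @export
gc_correct <- function(track, layout, min_bins = 100L) {
  stopifnot(inherits(track, "depth_track"), inherits(layout, "genome_layout"))
  if (all(track$raw_depth == 0)) {
    stop("degenerate input: all bin depths are zero")
  }
  bs <- layout$bin_size
  gc <- numeric(nrow(track))
  for (sc in unique(track$scaffold)) {
    sel <- track$scaffold == sc
    idx <- track$bin_start[sel] %/% bs + 1L
    gc_sc <- layout$gc[[sc]]
    if (is.null(gc_sc) || max(idx) > length(gc_sc)) {
      stop("no GC track for every bin of scaffold ", sc)
    }
    gc[sel] <- gc_sc[idx]
  }
  cls <- round(gc * 100)
  global_mean <- mean(track$raw_depth)
  cls_mean <- tapply(track$raw_depth, cls, mean)
  cls_n <- tapply(track$raw_depth, cls, length)
  factor <- global_mean / cls_mean
  factor[cls_n < min_bins | cls_mean == 0] <- 1
  track$corrected_depth <- as.numeric(track$raw_depth *
                                        factor[as.character(cls)])
  track
}

# Mean-shift split points for one scaffold's depth vector at bandwidth h.
# Each bin gets a drift direction: the sign of a Gaussian-kernel-weighted
# gradient, where neighbors are weighted both by genomic distance (scale h)
# and by depth similarity (Poisson-scale kernel), so bins are attracted
# toward neighbors at their own depth level. A split is placed between bins
# i and i+1 where bin i drifts left and bin i+1 drifts right.
# Returns split points as counts of bins before the boundary (in 1..n-1).
mean_shift_splits <- function(rd, h) {
  n <- length(rd)
  if (n < 2L) return(integer(0))
  kmax <- min(3L * h, n - 1L)
  d <- numeric(n)
  s2 <- pmax(rd, 1)
  for (k in seq_len(kmax)) {
    w <- k * exp(-k^2 / (2 * h^2))
    # right neighbors (offset +k) pull right, left neighbors pull left
    i <- seq_len(n - k)
    dr <- rd[i + k] - rd[i]
    sim <- exp(-dr^2 / (2 * (s2[i] + s2[i + k])))
    d[i] <- d[i] + w * sim          # +k neighbor of bin i
    d[i + k] <- d[i + k] - w * sim  # -k neighbor of bin i+k
  }
  which(d[-n] < 0 & d[-1L] > 0)
}

# Greedy boundary selection: given candidate split points, repeatedly merge
# the adjacent segment pair whose means differ least (largest p), until
# every remaining boundary is significant at `keep_p`. `test = "z"` uses
# the Poisson-variance z-test (the assembly pass: candidate fragments of
# one copy-number level coalesce while true level shifts survive);
# `test = "t"` uses the pooled two-sample t-test on the bin depths (the
# final re-merge contract). Because candidate boundaries are proposed by
# the data themselves, the assembly pass runs at a much stricter threshold
# than nominal.
greedy_merge <- function(rd, bounds, keep_p, test = c("z", "t")) {
  test <- match.arg(test)
  n <- length(rd)
  bounds <- sort(unique(c(0L, as.integer(bounds), n)))
  m <- length(bounds) - 1L
  if (m <= 1L) return(bounds)
  seg_n <- diff(bounds)
  cs <- c(0, cumsum(rd))
  cs2 <- c(0, cumsum(rd^2))
  seg_sum <- cs[bounds[-1L] + 1L] - cs[bounds[-(m + 1L)] + 1L]
  seg_sq <- cs2[bounds[-1L] + 1L] - cs2[bounds[-(m + 1L)] + 1L]
  p_of <- function(j) {
    if (test == "z") {
      pois_z_p(seg_n[j], seg_sum[j] / seg_n[j],
               seg_n[j + 1L], seg_sum[j + 1L] / seg_n[j + 1L])
    } else {
      pooled_t_p(seg_n[j], seg_sum[j], seg_sq[j],
                 seg_n[j + 1L], seg_sum[j + 1L], seg_sq[j + 1L])
    }
  }
  pvals <- vapply(seq_len(m - 1L), p_of, numeric(1))
  while (m > 1L) {
    j <- which.max(pvals)
    if (pvals[j] < keep_p) break
    seg_n[j] <- seg_n[j] + seg_n[j + 1L]
    seg_sum[j] <- seg_sum[j] + seg_sum[j + 1L]
    seg_sq[j] <- seg_sq[j] + seg_sq[j + 1L]
    seg_n <- seg_n[-(j + 1L)]
    seg_sum <- seg_sum[-(j + 1L)]
    seg_sq <- seg_sq[-(j + 1L)]
    bounds <- bounds[-(j + 1L)]
    pvals <- pvals[-j]
    m <- m - 1L
    if (j > 1L) pvals[j - 1L] <- p_of(j - 1L)
    if (j < m) pvals[j] <- p_of(j)
  }
  bounds
}

#' Segment a corrected depth track by multi-bandwidth mean shift
#'
#' Candidate breakpoints come from the mean-shift rule applied at every
#' bandwidth (smallest first): bins drift along the sign of a
#' Gaussian-kernel-weighted depth gradient (with a Poisson-scale depth
#' similarity kernel, so bins are attracted toward neighbors at their own
#' level) and a breakpoint is placed wherever the drift direction flips
#' from leftward to rightward. The pooled candidate boundaries are then
#' assembled bottom-up: adjacent fragments are merged greedily, least
#' significant difference first (Poisson-variance z-test), until every
#' surviving boundary separates segments at p < `boundary_p` — fragments
#' of one copy-number level coalesce while true level shifts freeze in
#' place. A final pass re-merges adjacent segments whose bin-depth
#' distributions do not differ by the pooled two-sample t-test
#' (p >= `merge_p`). Deterministic for fixed input and bandwidths.
#'
#' @param track a `depth_track` with `corrected_depth` filled in
#'   (see [gc_correct()]).
#' @param bandwidths integer bandwidths in bins, ascending (default
#'   `c(2, 4, 8, 16, 32)`).
#' @param merge_p re-merge threshold: adjacent segments with t-test
#'   p >= `merge_p` are merged (default 0.01).
#' @param boundary_p retention threshold on the Poisson z-test for
#'   candidate boundaries (default 1e-6): much stricter than `merge_p`
#'   because candidate boundaries are proposed by the data themselves,
#'   which inflates their nominal significance.
#' @return data.frame of segments: `scaffold`, `start_bin`, `end_bin`
#'   (half-open bin indices), `start`, `end` (bp), `mean_rd`, `n_bins`.
#'   Segments tile each scaffold without gaps.
#' @export
segment_track <- function(track, bandwidths = c(2L, 4L, 8L, 16L, 32L),
                          merge_p = 0.01, boundary_p = 1e-6) {
  stopifnot(inherits(track, "depth_track"))
  if (anyNA(track$corrected_depth)) {
    stop("corrected depths missing: run gc_correct() first")
  }
  bandwidths <- sort(as.integer(bandwidths))
  out <- list()
  for (sc in unique(track$scaffold)) {
    sel <- which(track$scaffold == sc)
    rd <- track$corrected_depth[sel]
    n <- length(rd)
    if (n == 0L) next
    splits <- integer(0)
    for (h in bandwidths) {
      splits <- union(splits, mean_shift_splits(rd, h))
    }
    # alternate the two merge criteria to a fixpoint: every surviving
    # boundary must be supported by both the Poisson z-test (strict) and
    # the pooled t-test re-merge contract
    bounds <- sort(unique(c(0L, splits, n)))
    repeat {
      b2 <- greedy_merge(rd, bounds, keep_p = boundary_p, test = "z")
      b2 <- greedy_merge(rd, b2, keep_p = merge_p, test = "t")
      if (identical(b2, bounds)) break
      bounds <- b2
    }
    m <- length(bounds) - 1L
    cs <- c(0, cumsum(rd))
    sb <- bounds[-(m + 1L)]
    eb <- bounds[-1L]
    out[[sc]] <- data.frame(
      scaffold = sc,
      start_bin = sb, end_bin = eb,
      start = track$bin_start[sel[sb + 1L]],
      end = track$bin_end[sel[eb]],
      mean_rd = (cs[eb + 1L] - cs[sb + 1L]) / (eb - sb),
      n_bins = eb - sb,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-wide depth summary for one sample
#'
#' Mean corrected depth over autosomal bins; sex scaffolds are excluded so
#' hemizygosity cannot bias the diploid baseline. This is the "effective
#' depth" used as denominator for copy-number normalization.
#'
#' @param track a `depth_track` with corrected depths.
#' @param sex_scaffolds character vector of scaffold names to exclude.
#' @param center `"mean"` (default) or `"median"`.
#' @return list with `mean_rd` (effective depth) and `n_bins`.
#' @export
genome_stats <- function(track, sex_scaffolds = character(), center = "mean") {
  stopifnot(inherits(track, "depth_track"))
  if (anyNA(track$corrected_depth)) {
    stop("corrected depths missing: run gc_correct() first")
  }
  keep <- !(track$scaffold %in% sex_scaffolds)
  x <- track$corrected_depth[keep]
  mu <- if (center == "median") stats::median(x) else mean(x)
  list(mean_rd = mu, n_bins = sum(keep))
}

#' Call CNVs from segments with the q0 / significance / length filters
#'
#' Each segment is normalized to the diploid scale,
#' `cn = 2 * mean_rd / genome_mean_rd`, and becomes a retained call iff
#' (a) its bin depths differ from the genome mean (one-sample t-test,
#' Benjamini-Hochberg-adjusted across all the sample's segments,
#' adjusted p < `alpha`), (b) its length is at least `min_length` bp, and
#' (c) its mean multi-mapping fraction q0 is at most `max_q0`. Boundaries
#' are already on bin edges from segmentation. Kind is `gain` for cn > 2,
#' `loss` for cn < 2.
#'
#' @param segments output of [segment_track()].
#' @param track the same sample's `depth_track`.
#' @param stats output of [genome_stats()] for this sample.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_length minimum call length in bp (default 1500).
#' @param max_q0 maximum mean q0 fraction (default 0.5).
#' @param min_cn_dev minimum copy-number deviation from diploid (default
#'   0.5, i.e. cn <= 1.5 or >= 2.5): large segments can differ from the
#'   genome mean statistically without representing a copy-number change,
#'   so calls must also deviate by at least half a copy — the conventional
#'   read-depth calling cutoff (depth ratio below 0.75 or above 1.25).
#' @return data.frame of calls: `sample_id`, `scaffold`, `start`, `end`,
#'   `kind`, `cn`, `p_value` (raw), `p_adj`, `q0_frac`, `n_bins`.
#' @export
call_cnvs <- function(segments, track, stats, alpha = 0.05,
                      min_length = 1500, max_q0 = 0.5, min_cn_dev = 0.5) {
  stopifnot(inherits(track, "depth_track"))
  mu <- stats$mean_rd
  if (!is.finite(mu) || mu <= 0) {
    stop("degenerate input: genome mean depth is zero")
  }
  sid <- attr(track, "sample_id") %||% NA_character_
  n_seg <- nrow(segments)
  p_raw <- numeric(n_seg)
  q0 <- numeric(n_seg)
  for (i in seq_len(n_seg)) {
    sel <- which(track$scaffold == segments$scaffold[i])
    idx <- sel[(segments$start_bin[i] + 1L):segments$end_bin[i]]
    p_raw[i] <- one_sample_t_p(track$corrected_depth[idx], mu)
    q0[i] <- mean(track$q0_frac[idx])
  }
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  cn <- 2 * segments$mean_rd / mu
  keep <- p_adj < alpha &
    (segments$end - segments$start) >= min_length &
    q0 <= max_q0 &
    abs(cn - 2) >= min_cn_dev
  calls <- data.frame(
    sample_id = sid,
    scaffold = segments$scaffold,
    start = segments$start,
    end = segments$end,
    kind = ifelse(cn > 2, "gain", "loss"),
    cn = cn,
    p_value = p_raw,
    p_adj = p_adj,
    q0_frac = q0,
    n_bins = segments$n_bins,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Full per-sample calling: GC correction, segmentation, filtering
#'
#' @param track a raw `depth_track`.
#' @param layout the `genome_layout`.
#' @param sex_scaffolds scaffolds excluded from the diploid baseline.
#' @param ... passed to [segment_track()] and [call_cnvs()]
#'   (`bandwidths`, `merge_p`, `alpha`, `min_length`, `max_q0`).
#' @return list with `track` (corrected), `segments`, `stats`, `calls`.
#' @export
call_sample <- function(track, layout, sex_scaffolds = character(), ...) {
  args <- list(...)
  track <- gc_correct(track, layout)
  seg_args <- args[intersect(names(args), c("bandwidths", "merge_p", "boundary_p"))]
  segments <- do.call(segment_track, c(list(track), seg_args))
  st <- genome_stats(track, sex_scaffolds = sex_scaffolds)
  call_args <- args[intersect(names(args),
                              c("alpha", "min_length", "max_q0",
                                "min_cn_dev"))]
  calls <- do.call(call_cnvs, c(list(segments, track, st), call_args))
  list(track = track, segments = segments, stats = st, calls = calls)
}
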