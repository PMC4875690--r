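#' Normalize an interval set
#'
#' Sorts per scaffold and unions overlapping intervals (half-open
#' coordinates; abutting intervals stay separate).
#'
#' @param intervals data.frame with `scaffold`, `start`, `end`.
#' @return normalized data.frame, sorted by scaffold and start.
#' @export
normalize_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(intervals)
  if (any(intervals$end <= intervals$start)) {
    stop("input error: intervals with end <= start")
  }
  out <- df0(GenomicRanges::reduce(
    gr0(intervals$scaffold, intervals$start, intervals$end),
    min.gapwidth = 0L))
  out[order(out$scaffold, out$start), , drop = FALSE]
}

# Internal: per-scaffold sorted SD intervals as IRanges for fast overlap.
split_iranges <- function(intervals) {
  sc <- unique(intervals$scaffold)
  out <- lapply(sc, function(s) {
    sel <- intervals$scaffold == s
    IRanges::IRanges(start = intervals$start[sel] + 1L,
                     end = intervals$end[sel])
  })
  names(out) <- sc
  out
}

# Internal: association statistic of CNVR intervals against a prepared SD
# IRanges list. big = logical mask of CNVRs to score (length filter applied
# by the caller); flanks are clipped to scaffold bounds.
sd_stat <- function(scaffold, start, end, sd_ir, lens, flank, statistic) {
  fs <- pmax(start - flank, 0)
  fe <- pmin(end + flank, lens[scaffold])
  hit <- logical(length(start))
  bp <- numeric(length(start))
  for (s in unique(scaffold)) {
    sel <- which(scaffold == s)
    ir <- IRanges::IRanges(start = fs[sel] + 1L, end = fe[sel])
    sd_s <- sd_ir[[s]]
    if (is.null(sd_s)) next
    if (statistic == "fraction") {
      hit[sel] <- IRanges::overlapsAny(ir, sd_s)
    } else {
      ov <- IRanges::findOverlaps(ir, sd_s)
      if (length(ov) > 0L) {
        w <- pmin(BiocGenerics::end(ir)[S4Vectors::queryHits(ov)],
                  BiocGenerics::end(sd_s)[S4Vectors::subjectHits(ov)]) -
          pmax(BiocGenerics::start(ir)[S4Vectors::queryHits(ov)],
               BiocGenerics::start(sd_s)[S4Vectors::subjectHits(ov)]) + 1L
        bp[sel] <- bp[sel] + as.numeric(
          tapply(w, factor(S4Vectors::queryHits(ov),
                           levels = seq_along(sel)), sum, default = 0))
      }
    }
  }
  if (statistic == "fraction") mean(hit) else sum(bp)
}

#' Fraction of large CNVRs overlapping segmental duplications
#'
#' The direct-overlap statistic: the fraction of CNVRs longer than
#' `min_len` whose interval, extended by `flank` bp on both sides (clipped
#' to scaffold bounds), intersects at least one SD interval by >= 1 bp.
#' Defaults give the direct >15 kb statistic; `flank = 5e6` gives the
#' flanked variant.
#'
#' @param cnvrs,sds data.frames with `scaffold`, `start`, `end` (normalized
#'   internally).
#' @param layout `genome_layout` or named scaffold-length vector (for flank
#'   clipping).
#' @param min_len strict length cut in bp (default 15000; use 0 for all).
#' @param flank extension in bp (default 0).
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(cnvrs, sds, layout, min_len = 15000, flank = 0) {
  if (nrow(cnvrs) == 0L) stop("undefined statistic: empty CNVR set")
  cnvrs <- normalize_intervals(cnvrs)
  sds <- if (nrow(sds) > 0L) normalize_intervals(sds) else sds
  lens <- scaffold_lengths(layout)
  big <- (cnvrs$end - cnvrs$start) > min_len
  if (!any(big)) stop("undefined statistic: no CNVRs longer than min_len")
  if (nrow(sds) == 0L) return(0)
  sd_ir <- split_iranges(sds)
  sd_stat(cnvrs$scaffold[big], cnvrs$start[big], cnvrs$end[big],
          sd_ir, lens, flank, "fraction")
}

#' Random-placement permutation test of CNVR-SD association
#'
#' Each permutation re-places every CNVR uniformly at random on its own
#' scaffold (length preserved, placements independent; placed intervals may
#' overlap each other), recomputes the association statistic, and the
#' empirical p-value uses the +1 correction
#' `p = (1 + #{null >= observed}) / (n_perm + 1)` (enrichment; `"less"`
#' tests depletion). Deterministic under `seed`.
#'
#' @param cnvrs,sds data.frames with `scaffold`, `start`, `end`.
#' @param layout `genome_layout` or named scaffold-length vector.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param flank extension in bp applied to (placed) CNVRs (default 0).
#' @param min_len strict length cut in bp (default 0: score all CNVRs).
#' @param statistic `"fraction"` (share of CNVRs touching an SD) or `"bp"`
#'   (total CNVR-SD intersection bp); the bp variant is near-continuous and
#'   preferred for calibration checks.
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return object of class `perm_test`: list with `observed`, `null_mean`,
#'   `null_sd`, `n_perm`, `p`, `seed`, `statistic`, `alternative`, `null`.
#' @export
permutation_test <- function(cnvrs, sds, layout, n_perm = 1000L, seed = 1L,
                             flank = 0, min_len = 0,
                             statistic = c("fraction", "bp"),
                             alternative = c("greater", "less")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (nrow(cnvrs) == 0L) stop("undefined statistic: empty CNVR set")
  cnvrs <- normalize_intervals(cnvrs)
  sds <- if (nrow(sds) > 0L) normalize_intervals(sds) else sds
  lens <- scaffold_lengths(layout)
  len_cn <- cnvrs$end - cnvrs$start
  if (any(len_cn > lens[cnvrs$scaffold])) {
    stop("placement error: CNVR longer than its scaffold")
  }
  big <- len_cn > min_len
  if (!any(big)) stop("undefined statistic: no CNVRs longer than min_len")
  sd_ir <- if (nrow(sds) > 0L) split_iranges(sds) else list()
  sc_b <- cnvrs$scaffold[big]
  len_b <- len_cn[big]
  max_start <- lens[sc_b] - len_b

  observed <- sd_stat(sc_b, cnvrs$start[big], cnvrs$end[big],
                      sd_ir, lens, flank, statistic)
  null <- numeric(n_perm)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_perm)) {
      st <- floor(stats::runif(length(len_b), 0, max_start + 1))
      null[b] <- sd_stat(sc_b, st, st + len_b, sd_ir, lens, flank, statistic)
    }
  })
  n_extreme <- if (alternative == "greater") sum(null >= observed)
               else sum(null <= observed)
  structure(list(
    observed = observed,
    null_mean = mean(null),
    null_sd = stats::sd(null),
    n_perm = as.integer(n_perm),
    p = (1 + n_extreme) / (n_perm + 1),
    seed = as.integer(seed),
    statistic = statistic,
    alternative = alternative,
    null = null
  ), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test (", x$statistic, ", ", x$alternative, "): observed = ",
      signif(x$observed, 4), ", null = ", signif(x$null_mean, 4), " +/- ",
      signif(x$null_sd, 4), " (n_perm = ", x$n_perm, "), p = ",
      signif(x$p, 4), "\n", sep = "")
  invisible(x)
}
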