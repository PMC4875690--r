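#' Classify a CNVR from its contributing call kinds
#'
#' @param kinds character vector of `"gain"` / `"loss"` from the calls
#'   contributing to one CNVR.
#' @return `"gain"`, `"loss"`, or `"both"`.
#' @export
classify_type <- function(kinds) {
  if (length(kinds) == 0L) stop("no contributing calls")
  u <- unique(kinds)
  if (!all(u %in% c("gain", "loss"))) stop("kinds must be 'gain' or 'loss'")
  if (length(u) == 2L) "both" else u
}

#' Merge per-sample CNV calls into cross-sample CNV regions
#'
#' CNVRs are the connected components of the overlap graph of all samples'
#' calls: calls sharing at least 1 bp (half-open coordinates, so abutting
#' calls do not merge) are chained, and each CNVR spans from the component's
#' minimum start to its maximum end. Support counts *distinct samples* with
#' a contributing call; CNVRs supported by fewer than `min_support` samples
#' are removed.
#'
#' @param calls data.frame of calls from all samples (columns `sample_id`,
#'   `scaffold`, `start`, `end`, `kind`, and optionally `cn`).
#' @param min_support minimum number of distinct supporting samples
#'   (default 4).
#' @return data.frame of CNVRs (`id`, `scaffold`, `start`, `end`, `type`,
#'   `support`, `n_calls`) sorted by position, with attribute
#'   `"contributing"`: a data.frame mapping `cnvr_id` to rows of `calls`
#'   (`call_row`, `sample_id`, `kind`).
#' @export
merge_calls <- function(calls, min_support = 4L) {
  if (nrow(calls) == 0L) {
    res <- data.frame(id = character(), scaffold = character(),
                      start = numeric(), end = numeric(), type = character(),
                      support = integer(), n_calls = integer(),
                      stringsAsFactors = FALSE)
    attr(res, "contributing") <- data.frame(cnvr_id = character(),
                                            call_row = integer(),
                                            sample_id = character(),
                                            kind = character())
    return(res)
  }
  if (any(calls$end <= calls$start)) {
    stop("input error: calls with end <= start")
  }
  gr <- gr0(calls$scaffold, calls$start, calls$end)
  # min.gapwidth = 0 merges overlapping ranges only; abutting half-open
  # intervals (gap 0 in closed coordinates) stay separate
  comp <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, comp)
  stopifnot(length(hits) == nrow(calls))
  comp_of <- S4Vectors::subjectHits(hits)

  cdf <- df0(comp)
  support <- vapply(seq_len(nrow(cdf)), function(i)
    length(unique(calls$sample_id[comp_of == i])), integer(1))
  n_calls <- tabulate(comp_of, nbins = nrow(cdf))
  type <- vapply(seq_len(nrow(cdf)), function(i)
    classify_type(calls$kind[comp_of == i]), character(1))

  keep <- which(support >= min_support)
  cdf <- cdf[keep, , drop = FALSE]
  ord <- order(cdf$scaffold, cdf$start)
  cdf <- cdf[ord, , drop = FALSE]
  kept_comp <- keep[ord]
  res <- data.frame(
    id = sprintf("cnvr_%05d", seq_along(kept_comp)),
    scaffold = cdf$scaffold, start = cdf$start, end = cdf$end,
    type = type[kept_comp], support = support[kept_comp],
    n_calls = n_calls[kept_comp],
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  contrib_rows <- which(comp_of %in% kept_comp)
  contributing <- data.frame(
    cnvr_id = res$id[match(comp_of[contrib_rows], kept_comp)],
    call_row = contrib_rows,
    sample_id = calls$sample_id[contrib_rows],
    kind = calls$kind[contrib_rows],
    stringsAsFactors = FALSE
  )
  attr(res, "contributing") <- contributing
  res
}

#' Build the CNVR x sample copy-number matrix from depth
#'
#' Every cell is depth-derived (never imputed): the value for CNVR r and
#' sample s is `2 * mean corrected depth of s over r / effective depth of
#' s`, where the effective depth is the sample's genome-wide mean corrected
#' autosomal depth. Samples without a call in a region therefore get a
#' value near 2 if truly diploid, and real dosage otherwise.
#'
#' @param cnvrs data.frame from [merge_calls()].
#' @param tracks named list of corrected `depth_track`s (all samples).
#' @param sex_scaffolds scaffolds excluded from effective depth.
#' @return numeric matrix, rows = CNVR ids, columns = sample ids.
#' @export
build_cn_matrix <- function(cnvrs, tracks, sex_scaffolds = character()) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  eff <- vapply(tracks, function(tr)
    genome_stats(tr, sex_scaffolds = sex_scaffolds)$mean_rd, numeric(1))
  mat <- matrix(NA_real_, nrow(cnvrs), length(tracks),
                dimnames = list(cnvrs$id, names(tracks)))
  # index bins per scaffold once per track
  for (s in names(tracks)) {
    tr <- tracks[[s]]
    if (anyNA(tr$corrected_depth)) {
      stop("corrected depths missing for sample ", s)
    }
    bs <- attr(tr, "bin_size")
    sc_rows <- split(seq_len(nrow(tr)), tr$scaffold)
    for (i in seq_len(nrow(cnvrs))) {
      rows <- sc_rows[[cnvrs$scaffold[i]]]
      if (is.null(rows)) {
        stop("coverage error: sample ", s, " has no bins on ",
             cnvrs$scaffold[i])
      }
      b0 <- cnvrs$start[i] %/% bs + 1L
      b1 <- as.integer(ceiling(cnvrs$end[i] / bs))
      if (b1 > length(rows)) {
        stop("coverage error: sample ", s, " does not cover ",
             cnvrs$scaffold[i], ":", cnvrs$start[i], "-", cnvrs$end[i])
      }
      mat[i, s] <- 2 * mean(tr$corrected_depth[rows[b0:b1]]) / eff[[s]]
    }
  }
  mat
}
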