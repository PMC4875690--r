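#' Copy number from qPCR by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target - Ct_reference)_sample - (Ct_target -
#' Ct_reference)_calibrator`; against a diploid reference locus the copy
#' number is `2 * 2^(-ddCt)`, so one cycle of advantage doubles the dosage
#' and the calibrator is CN 2 by construction.
#'
#' @param ct_target,ct_reference sample Ct values (cycles, > 0).
#' @param cal_ct_target,cal_ct_reference calibrator Ct values for the same
#'   primer pairs.
#' @return estimated copy number (vectorized).
#' @export
ddct_copy_number <- function(ct_target, ct_reference,
                             cal_ct_target, cal_ct_reference) {
  if (missing(cal_ct_target) || missing(cal_ct_reference)) {
    stop("input error: calibrator Ct values are required")
  }
  vals <- c(ct_target, ct_reference, cal_ct_target, cal_ct_reference)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all Ct values must be finite and > 0")
  }
  ddct <- (ct_target - ct_reference) - (cal_ct_target - cal_ct_reference)
  2 * 2^(-ddct)
}

#' cv% concordance between two copy-number predictions
#'
#' The coefficient of variation of the pair: sample standard deviation
#' (n - 1 denominator, so `|a - b| / sqrt(2)`) divided by the pair mean.
#' The pair is concordant ("acceptable") when cv < `cv_max`.
#'
#' @param cn_primary,cn_highdepth the two copy-number estimates (>= 0, not
#'   both 0).
#' @param cv_max acceptance gate (default 0.25).
#' @param denom `"n-1"` (sample sd, default) or `"n"` (population sd,
#'   `|a - b| / 2`).
#' @return list with `cn_primary`, `cn_highdepth`, `cv`, `acceptable`.
#' @export
cv_concordance <- function(cn_primary, cn_highdepth, cv_max = 0.25,
                           denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  if (any(cn_primary < 0) || any(cn_highdepth < 0)) {
    stop("copy numbers must be >= 0")
  }
  m <- (cn_primary + cn_highdepth) / 2
  if (any(m == 0)) stop("undefined cv: pair mean is 0")
  s <- abs(cn_primary - cn_highdepth) / (if (denom == "n-1") sqrt(2) else 2)
  cv <- s / m
  list(cn_primary = cn_primary, cn_highdepth = cn_highdepth, cv = cv,
       acceptable = cv < cv_max)
}

#' Fraction of calls supported by a high-depth call set
#'
#' A primary call is supported when at least one high-depth call of the
#' same sample overlaps it by >= 1 bp and (when `require_cv`) the cv of the
#' two copy-number estimates is below `cv_max`.
#'
#' @param calls_primary,calls_highdepth call data.frames (`sample_id`,
#'   `scaffold`, `start`, `end`, `cn`).
#' @param cv_max cv gate (default 0.25).
#' @param require_cv apply the cv gate in addition to overlap
#'   (default TRUE).
#' @return list with `supported_fraction`, `n_primary`, `n_supported`, and
#'   `per_call` (logical vector).
#' @export
concordance_report <- function(calls_primary, calls_highdepth,
                               cv_max = 0.25, require_cv = TRUE) {
  if (nrow(calls_primary) == 0L) {
    stop("undefined fraction: empty primary call set")
  }
  supported <- logical(nrow(calls_primary))
  if (nrow(calls_highdepth) > 0L) {
    gp <- gr0(calls_primary$scaffold, calls_primary$start, calls_primary$end)
    gh <- gr0(calls_highdepth$scaffold, calls_highdepth$start,
              calls_highdepth$end)
    hits <- GenomicRanges::findOverlaps(gp, gh)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    same_sample <- calls_primary$sample_id[qh] ==
      calls_highdepth$sample_id[sh]
    qh <- qh[same_sample]; sh <- sh[same_sample]
    ok <- if (require_cv) {
      a <- calls_primary$cn[qh]
      b <- calls_highdepth$cn[sh]
      both_zero <- a == 0 & b == 0  # identical zero predictions agree
      ok_cv <- both_zero
      if (any(!both_zero)) {
        ok_cv[!both_zero] <- cv_concordance(a[!both_zero], b[!both_zero],
                                            cv_max = cv_max)$acceptable
      }
      ok_cv
    } else {
      rep(TRUE, length(qh))
    }
    supported[unique(qh[ok])] <- TRUE
  }
  list(supported_fraction = mean(supported),
       n_primary = nrow(calls_primary),
       n_supported = sum(supported),
       per_call = supported)
}
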