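#' Evaluate caller output against a planted truth set
#'
#' Scores every (event, carrier sample) pair of the truth: the pair is
#' recovered when the sample has a call on the event's scaffold with both
#' breakpoints within `tol_bins` bins of the true ones and a copy-number
#' error of at most `cn_tol`. Precision is scored per emitted call: a call
#' is a false positive when it overlaps (by >= 1 bp) no event carried by
#' its sample.
#'
#' @param calls combined call data.frame (all samples).
#' @param truth a `cnv_truth`.
#' @param layout the `genome_layout` (bin size for the tolerance).
#' @param tol_bins breakpoint tolerance in bins (default 2).
#' @param cn_tol copy-number tolerance (default 0.5).
#' @return list with `recall`, `false_call_rate`, `n_truth_pairs`,
#'   `n_recovered`, `n_calls`, `n_false_calls`, `mean_cn_error` (over
#'   matched pairs), and `pairs` (per-pair data.frame).
#' @export
evaluate_recovery <- function(calls, truth, layout, tol_bins = 2L,
                              cn_tol = 0.5) {
  bs <- layout$bin_size
  tol <- tol_bins * bs
  ev <- truth$events
  pairs <- list()
  for (i in seq_len(nrow(ev))) {
    carriers <- colnames(truth$cn)[truth$cn[i, ] != 2L]
    if (length(carriers) == 0L) next
    pairs[[i]] <- data.frame(
      event_id = ev$event_id[i], scaffold = ev$scaffold[i],
      start = ev$start[i], end = ev$end[i],
      sample_id = carriers,
      true_cn = as.integer(truth$cn[i, carriers]),
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("truth set has no carrier pairs to evaluate")
  }
  pairs$recovered <- FALSE
  pairs$cn_error <- NA_real_
  for (j in seq_len(nrow(pairs))) {
    cand <- calls[calls$sample_id == pairs$sample_id[j] &
                    calls$scaffold == pairs$scaffold[j] &
                    abs(calls$start - pairs$start[j]) <= tol &
                    abs(calls$end - pairs$end[j]) <= tol, , drop = FALSE]
    if (nrow(cand) == 0L) next
    err <- abs(cand$cn - pairs$true_cn[j])
    if (min(err) <= cn_tol) {
      pairs$recovered[j] <- TRUE
      pairs$cn_error[j] <- min(err)
    }
  }
  # false calls: no >= 1 bp overlap with any event carried by the sample
  false_call <- logical(nrow(calls))
  for (k in seq_len(nrow(calls))) {
    s <- calls$sample_id[k]
    carried <- ev[truth$cn[, s] != 2L & ev$scaffold == calls$scaffold[k], ,
                  drop = FALSE]
    false_call[k] <- !(nrow(carried) > 0 &&
                         any(calls$start[k] < carried$end &
                               calls$end[k] > carried$start))
  }
  list(
    recall = mean(pairs$recovered),
    false_call_rate = if (nrow(calls) > 0) mean(false_call) else NA_real_,
    n_truth_pairs = nrow(pairs),
    n_recovered = sum(pairs$recovered),
    n_calls = nrow(calls),
    n_false_calls = sum(false_call),
    mean_cn_error = mean(pairs$cn_error[pairs$recovered]),
    pairs = pairs
  )
}
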