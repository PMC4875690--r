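#' V_ST differentiation statistic for copy number
#'
#' `V_ST = (V_T - V_S) / V_T`, where `V_T` is the total variance in copy
#' number of the pooled samples and `V_S` the average of the within-group
#' variances weighted by sample size. Variances are population variances
#' (denominator n) by default, matching the statistic's usual definition;
#' `V_T = 0` (all values identical) makes the statistic undefined and is
#' flagged.
#'
#' @param cn_a,cn_b numeric copy-number vectors for the two groups, each of
#'   length >= 2.
#' @param var_type `"population"` (denominator n, default) or `"sample"`
#'   (denominator n - 1).
#' @return list with `v_t`, `v_s`, `v_st`, and `defined` (FALSE when
#'   `v_t == 0`, in which case `v_st` is reported as 0).
#' @export
vst <- function(cn_a, cn_b, var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  n_a <- length(cn_a)
  n_b <- length(cn_b)
  if (n_a < 2L || n_b < 2L) {
    stop("insufficient data: each group needs at least 2 samples")
  }
  vf <- if (var_type == "population") {
    function(x) mean((x - mean(x))^2)
  } else {
    stats::var
  }
  v_t <- vf(c(cn_a, cn_b))
  v_s <- (n_a * vf(cn_a) + n_b * vf(cn_b)) / (n_a + n_b)
  if (v_t == 0) {
    list(v_t = 0, v_s = v_s, v_st = 0, defined = FALSE)
  } else {
    list(v_t = v_t, v_s = v_s, v_st = (v_t - v_s) / v_t, defined = TRUE)
  }
}

#' Two-sample t-test on copy-number vectors
#'
#' Student's pooled-variance two-sided test by default (Welch optional).
#' Degenerate inputs collapse to point comparisons: zero pooled variance
#' gives p = 1 for equal means and p = 0 otherwise.
#'
#' @param cn_a,cn_b numeric vectors, each of length >= 2.
#' @param welch use Welch's unequal-variance test instead of the pooled one.
#' @return two-sided p-value in `[0, 1]`.
#' @export
cn_ttest <- function(cn_a, cn_b, welch = FALSE) {
  if (length(cn_a) < 2L || length(cn_b) < 2L) {
    stop("insufficient data: each group needs at least 2 samples")
  }
  if (welch) {
    v_a <- stats::var(cn_a)
    v_b <- stats::var(cn_b)
    if (v_a + v_b <= 0) {
      return(if (isTRUE(all.equal(mean(cn_a), mean(cn_b)))) 1 else 0)
    }
    return(stats::t.test(cn_a, cn_b, var.equal = FALSE)$p.value)
  }
  pooled_t_p(length(cn_a), sum(cn_a), sum(cn_a^2),
             length(cn_b), sum(cn_b), sum(cn_b^2))
}

#' Select population-differentiated CNVRs (top-V_ST + t-test criterion)
#'
#' Computes V_ST and the Student's t-test p for every CNVR and flags as
#' differentiated those in the top `top_frac` of all *defined* V_ST values
#' (ties at the threshold included) that also have t-test p < `alpha`.
#' The V_ST threshold is the `1 - top_frac` quantile with linear
#' interpolation. CNVRs with undefined V_ST are never selected.
#'
#' @param cn_matrix CNVR x sample copy-number matrix
#'   (see [build_cn_matrix()]).
#' @param assignment either a named character vector mapping sample id to
#'   group label, or a data.frame with columns `sample_id` and `group` (or
#'   `population`). Exactly two groups; every matrix column must be
#'   assigned.
#' @param top_frac fraction of top V_ST values to consider (default 0.05).
#' @param alpha t-test p threshold (default 0.05).
#' @param var_type passed to [vst()].
#' @param welch passed to [cn_ttest()].
#' @return data.frame with one row per CNVR: `cnvr_id`, `v_t`, `v_s`,
#'   `v_st`, `defined`, `t_p`, `selected`; attribute `"v_st_threshold"`.
#' @export
select_differentiated <- function(cn_matrix, assignment, top_frac = 0.05,
                                  alpha = 0.05,
                                  var_type = c("population", "sample"),
                                  welch = FALSE) {
  var_type <- match.arg(var_type)
  if (is.data.frame(assignment)) {
    gcol <- intersect(c("group", "population"), names(assignment))[1]
    if (is.na(gcol)) stop("assignment data.frame needs a 'group' or 'population' column")
    assignment <- stats::setNames(as.character(assignment[[gcol]]),
                                  assignment$sample_id)
  }
  samples <- colnames(cn_matrix)
  if (!all(samples %in% names(assignment))) {
    stop("every matrix column must have a group assignment")
  }
  grp <- assignment[samples]
  groups <- unique(grp)
  if (length(groups) != 2L) stop("exactly 2 groups required, got ", length(groups))
  ia <- which(grp == groups[1])
  ib <- which(grp == groups[2])
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("insufficient data: each group needs at least 2 samples")
  }
  n <- nrow(cn_matrix)
  v_t <- v_s <- v_st <- t_p <- numeric(n)
  defined <- logical(n)
  for (i in seq_len(n)) {
    a <- cn_matrix[i, ia]
    b <- cn_matrix[i, ib]
    v <- vst(a, b, var_type = var_type)
    v_t[i] <- v$v_t; v_s[i] <- v$v_s; v_st[i] <- v$v_st
    defined[i] <- v$defined
    t_p[i] <- cn_ttest(a, b, welch = welch)
  }
  thr <- if (any(defined)) {
    stats::quantile(v_st[defined], probs = 1 - top_frac, names = FALSE,
                    type = 7)
  } else {
    Inf
  }
  res <- data.frame(
    cnvr_id = rownames(cn_matrix) %||% as.character(seq_len(n)),
    v_t = v_t, v_s = v_s, v_st = v_st, defined = defined, t_p = t_p,
    selected = defined & v_st >= thr & t_p < alpha,
    stringsAsFactors = FALSE
  )
  attr(res, "v_st_threshold") <- thr
  res
}
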