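# Internal helpers shared across modules.

# Convert BED-like 0-based half-open intervals to GRanges (1-based closed).
gr0 <- function(scaffold, start, end, seqlengths = NULL) {
  stopifnot(all(end > start))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(scaffold),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end))
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

# Back to 0-based half-open data.frame.
df0 <- function(gr) {
  data.frame(
    scaffold = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
}

# Scaffold length lookup from a genome_layout or a named numeric vector.
scaffold_lengths <- function(layout) {
  if (inherits(layout, "genome_layout")) {
    stats::setNames(layout$scaffolds$length, layout$scaffolds$name)
  } else if (is.numeric(layout) && !is.null(names(layout))) {
    layout
  } else {
    stop("`layout` must be a genome_layout or a named numeric vector of scaffold lengths")
  }
}

# Two-sample pooled-variance (Student's) t-test from sufficient statistics.
# Degenerate branches: fewer than 3 observations in total -> p = 1 (cannot
# test); zero pooled variance -> p = 1 if means equal, 0 otherwise.
pooled_t_p <- function(n1, sum1, sumsq1, n2, sum2, sumsq2) {
  m1 <- sum1 / n1
  m2 <- sum2 / n2
  if (n1 + n2 < 3L) return(1)
  ss <- max(sumsq1 - n1 * m1^2, 0) + max(sumsq2 - n2 * m2^2, 0)
  df <- n1 + n2 - 2L
  sp2 <- ss / df
  if (sp2 <= .Machine$double.eps * max(m1^2, m2^2, 1)) {
    return(if (isTRUE(all.equal(m1, m2))) 1 else 0)
  }
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tt), df)
}

# One-sample t-test of values against a fixed mean mu. Degenerate: a single
# observation or zero variance collapses to the point comparison.
one_sample_t_p <- function(x, mu) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(if (isTRUE(all.equal(m, mu))) 1 else 1)
  v <- stats::var(x)
  if (v <= .Machine$double.eps * max(m^2, 1)) {
    return(if (isTRUE(all.equal(m, mu))) 1 else 0)
  }
  tt <- (m - mu) / sqrt(v / n)
  2 * stats::pt(-abs(tt), n - 1L)
}

# Two-sample z-test using the Poisson mean-variance relation (read counts
# per bin are approximately Poisson, so the variance of a segment mean is
# mean/n). The variance is evaluated under the null of a common rate — the
# pooled mean — so a short fluctuation cannot shrink its own variance
# estimate. More powerful than a t-test on short segments because the
# variance is not estimated from the few bins themselves.
pois_z_p <- function(n1, m1, n2, m2, eps = 1e-3) {
  m0 <- pmax((n1 * m1 + n2 * m2) / (n1 + n2), eps)
  v <- m0 / n1 + m0 / n2
  2 * stats::pnorm(-abs(m1 - m2) / sqrt(v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
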