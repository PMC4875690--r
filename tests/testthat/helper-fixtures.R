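# Shared in-code fixtures: hand-built depth tracks and layouts small enough
# to reason about exactly.

make_track <- function(depth, bin_size = 500L, scaffold = "s1",
                       q0 = 0.02, sample_id = "samp", corrected = TRUE) {
  n <- length(depth)
  if (length(scaffold) == 1L) scaffold <- rep(scaffold, n)
  bin_start <- integer(n)
  for (sc in unique(scaffold)) {
    idx <- which(scaffold == sc)
    bin_start[idx] <- (seq_along(idx) - 1L) * bin_size
  }
  tr <- data.frame(
    scaffold = scaffold, bin_start = bin_start,
    bin_end = bin_start + bin_size,
    raw_depth = depth,
    corrected_depth = if (corrected) depth else NA_real_,
    q0_frac = rep_len(q0, n),
    stringsAsFactors = FALSE
  )
  attr(tr, "sample_id") <- sample_id
  attr(tr, "bin_size") <- bin_size
  class(tr) <- c("depth_track", "data.frame")
  tr
}

make_layout <- function(n_bins, bin_size = 500L, gc = 0.45,
                        scaffold = "s1") {
  if (length(n_bins) == 1L && length(scaffold) == 1L) {
    n_bins <- stats::setNames(n_bins, scaffold)
  }
  gc_list <- lapply(n_bins, function(nb) rep_len(gc, nb))
  structure(
    list(
      scaffolds = data.frame(name = names(n_bins),
                             length = as.numeric(n_bins) * bin_size,
                             stringsAsFactors = FALSE),
      bin_size = as.integer(bin_size),
      gc = gc_list
    ),
    class = "genome_layout"
  )
}

# Independent brute-force V_ST: direct arithmetic, no shared code with vst().
vst_brute <- function(a, b) {
  pool <- c(a, b)
  mt <- sum(pool) / length(pool)
  v_t <- sum((pool - mt)^2) / length(pool)
  va <- sum((a - sum(a) / length(a))^2) / length(a)
  vb <- sum((b - sum(b) / length(b))^2) / length(b)
  v_s <- (length(a) * va + length(b) * vb) / (length(a) + length(b))
  if (v_t == 0) NA_real_ else (v_t - v_s) / v_t
}

# Independent connected-component interval merger (O(n^2) overlap graph +
# igraph components).
merge_oracle <- function(calls) {
  out <- list()
  for (sc in unique(calls$scaffold)) {
    d <- calls[calls$scaffold == sc, , drop = FALSE]
    n <- nrow(d)
    adj <- outer(seq_len(n), seq_len(n), function(i, j)
      d$start[i] < d$end[j] & d$end[i] > d$start[j])
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      m <- d[comp == cid, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, start = min(m$start), end = max(m$end),
        support = length(unique(m$sample_id)),
        type = if (length(unique(m$kind)) > 1) "both" else unique(m$kind),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$start), , drop = FALSE]
}
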