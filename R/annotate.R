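#' Genes primarily covered by CNVRs (>50% rule)
#'
#' A gene is retained when the union of all CNVRs covers strictly more than
#' half of its length (so a gene split across several adjacent CNVRs counts
#' once, and exactly-50% coverage is excluded). Each retained gene is
#' reported once per overlapping CNVR, together with its union covered
#' fraction at full precision.
#'
#' @param genes data.frame with `gene_id`, `scaffold`, `start`, `end`
#'   (0-based half-open bp).
#' @param cnvrs data.frame with `id`, `scaffold`, `start`, `end`.
#' @param layout optional `genome_layout` (or named length vector); when
#'   given, genes on scaffolds absent from the layout raise a lookup error.
#' @param min_fraction retention threshold, strict (default 0.5).
#' @return data.frame `gene_id`, `cnvr_id`, `covered_fraction`.
#' @export
genes_in_cnvrs <- function(genes, cnvrs, layout = NULL, min_fraction = 0.5) {
  if (!is.null(layout)) {
    lens <- scaffold_lengths(layout)
    bad <- setdiff(unique(genes$scaffold), names(lens))
    if (length(bad) > 0) {
      stop("lookup error: gene(s) on unknown scaffold: ",
           paste(bad, collapse = ", "))
    }
  }
  empty <- data.frame(gene_id = character(), cnvr_id = character(),
                      covered_fraction = numeric(), stringsAsFactors = FALSE)
  if (nrow(genes) == 0L || nrow(cnvrs) == 0L) return(empty)
  g_gr <- gr0(genes$scaffold, genes$start, genes$end)
  r_gr <- gr0(cnvrs$scaffold, cnvrs$start, cnvrs$end)
  r_union <- GenomicRanges::reduce(r_gr)
  hits <- GenomicRanges::findOverlaps(g_gr, r_union)
  if (length(hits) == 0L) return(empty)
  ov <- GenomicRanges::pintersect(g_gr[S4Vectors::queryHits(hits)],
                                  r_union[S4Vectors::subjectHits(hits)])
  cov_bp <- tapply(BiocGenerics::width(ov), S4Vectors::queryHits(hits), sum)
  gene_idx <- as.integer(names(cov_bp))
  frac <- as.numeric(cov_bp) / (genes$end[gene_idx] - genes$start[gene_idx])
  keep_gene <- gene_idx[frac > min_fraction]
  frac_of <- stats::setNames(frac, gene_idx)
  if (length(keep_gene) == 0L) return(empty)
  pair_hits <- GenomicRanges::findOverlaps(g_gr[keep_gene], r_gr)
  data.frame(
    gene_id = genes$gene_id[keep_gene][S4Vectors::queryHits(pair_hits)],
    cnvr_id = cnvrs$id[S4Vectors::subjectHits(pair_hits)],
    covered_fraction = unname(
      frac_of[as.character(keep_gene)][S4Vectors::queryHits(pair_hits)]),
    stringsAsFactors = FALSE
  )
}

#' Hypergeometric term enrichment with FDR control
#'
#' For every functional term with at least one background gene, tests
#' over-representation in the study set with the upper-tail hypergeometric
#' probability `P(X >= k)` and adjusts across terms by Benjamini-Hochberg.
#'
#' @param study_genes character vector (must be a subset of background).
#' @param background_genes character vector (the gene universe).
#' @param term_map data.frame with `gene_id`, `term_id`.
#' @param alpha adjusted-p significance cut-off (default 0.05).
#' @return data.frame sorted by adjusted p: `term_id`, `k` (study genes
#'   with term), `n` (study size), `K` (background genes with term), `N`
#'   (background size), `p`, `p_adj`, `significant`.
#' @export
enrich_terms <- function(study_genes, background_genes, term_map,
                         alpha = 0.05) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  if (length(background_genes) == 0L) stop("background is empty")
  if (!all(study_genes %in% background_genes)) {
    stop("input error: study genes must be a subset of the background")
  }
  tm <- term_map[term_map$gene_id %in% background_genes, , drop = FALSE]
  tm <- unique(tm[, c("gene_id", "term_id")])
  N <- length(background_genes)
  n <- length(study_genes)
  terms <- unique(tm$term_id)
  K <- vapply(terms, function(t)
    length(unique(tm$gene_id[tm$term_id == t])), integer(1))
  k <- vapply(terms, function(t)
    sum(unique(tm$gene_id[tm$term_id == t]) %in% study_genes), integer(1))
  keep <- K > 0
  terms <- terms[keep]; K <- K[keep]; k <- k[keep]
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(term_id = terms, k = k, n = n, K = K, N = N,
                    p = p, p_adj = p_adj, significant = p_adj < alpha,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_adj, res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
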