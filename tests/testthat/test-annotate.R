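gene_df <- function(id, start, end, scaffold = "sc") {
  data.frame(gene_id = id, scaffold = scaffold, start = start, end = end,
             stringsAsFactors = FALSE)
}
cnvr_df <- function(id, start, end, scaffold = "sc") {
  data.frame(id = id, scaffold = scaffold, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("the >50% gene-coverage rule is strict and union-based", {
  cnvrs <- cnvr_df(c("r1", "r2"), c(1000, 5000), c(3000, 8000))
  genes <- gene_df(
    c("inside", "g40", "g50", "g51"),
    c(1200, 2600, 2000, 2000),
    c(2200, 3600, 4000, 3980)
  )
  # inside: fully covered; g40: 400/1000; g50: exactly 1000/2000; g51:
  # 1000/1980 (> 50%)
  hits <- genes_in_cnvrs(genes, cnvrs)
  expect_setequal(unique(hits$gene_id), c("inside", "g51"))
  expect_equal(hits$covered_fraction[hits$gene_id == "inside"], 1.0)
  expect_equal(hits$covered_fraction[hits$gene_id == "g51"], 1000 / 1980)

  # a gene split across several CNVRs counts its union coverage
  split_gene <- gene_df("span", 2000, 6000)
  hits2 <- genes_in_cnvrs(split_gene, cnvrs)
  # covered: [2000,3000) + [5000,6000) = 2000 of 4000 -> exactly 50%: dropped
  expect_equal(nrow(hits2), 0L)
  hits3 <- genes_in_cnvrs(gene_df("span", 2100, 6000), cnvrs)
  # 1900 of 3900 < 50%: dropped
  expect_equal(nrow(hits3), 0L)
  # [2500,7500): covered [2500,3000) + [5000,7500) = 3000 of 5000 = 60%
  hits4 <- genes_in_cnvrs(gene_df("span", 2500, 7500), cnvrs)
  expect_equal(unique(hits4$gene_id), "span")
  expect_equal(hits4$covered_fraction, rep(3000 / 5000, 2))
  expect_equal(sort(hits4$cnvr_id), c("r1", "r2"))

  # invariance to splitting a CNVR into adjacent pieces
  pieces <- cnvr_df(c("a", "b", "c"), c(1000, 1700, 5000),
                    c(1700, 3000, 8000))
  g <- gene_df("inside", 1200, 2200)
  expect_equal(genes_in_cnvrs(g, pieces)$covered_fraction[1], 1.0)

  # unknown scaffold lookup error when a layout is supplied
  expect_error(
    genes_in_cnvrs(gene_df("g", 0, 100, scaffold = "nope"), cnvrs,
                   layout = c(sc = 10000)),
    "lookup error")
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  # N=20, K=5, n=5, k=5: p = C(5,5) C(15,0) / C(20,5) = 1/15504
  bg <- paste0("g", 1:20)
  term_map <- data.frame(gene_id = bg[1:5], term_id = "T1",
                         stringsAsFactors = FALSE)
  res <- enrich_terms(bg[1:5], bg, term_map)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)

  # oracle over 24 enumerated cases
  hyper_oracle <- function(N, K, n, k) {
    kk <- k:min(n, K)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
  }
  cases <- expand.grid(N = c(20, 40), K = c(3, 5, 10), n = c(5, 8),
                       k = c(1, 2))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    bg <- paste0("g", seq_len(cs$N))
    tm <- data.frame(gene_id = bg[seq_len(cs$K)], term_id = "T",
                     stringsAsFactors = FALSE)
    study <- c(bg[seq_len(cs$k)], bg[(cs$K + 1):(cs$K + cs$n - cs$k)])
    got <- enrich_terms(study, bg, tm)
    expect_equal(got$k, cs$k)
    expect_equal(got$p, hyper_oracle(cs$N, cs$K, cs$n, cs$k),
                 tolerance = 1e-12)
  }

  # study == background: no enrichment possible
  bg <- paste0("g", 1:10)
  tm <- data.frame(gene_id = bg[1:4], term_id = "T1",
                   stringsAsFactors = FALSE)
  expect_equal(enrich_terms(bg, bg, tm)$p, 1)

  expect_error(enrich_terms(c("zz"), bg, tm), "subset")
})

test_that("enrichment p is monotone in k and BH matches the step-up oracle", {
  p_at <- function(k) {
    bg <- paste0("g", 1:40)
    tm <- data.frame(gene_id = bg[1:10], term_id = "T",
                     stringsAsFactors = FALSE)
    study <- c(bg[seq_len(k)], bg[11:(10 + 8 - k)])
    enrich_terms(study, bg, tm)$p
  }
  ps <- vapply(1:8, p_at, numeric(1))
  expect_true(all(diff(ps) < 0))

  # BH step-up by hand: {0.01, 0.02, 0.03, 0.04} -> all 0.04
  bh_hand <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_hand(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))

  # enrich_terms applies BH across terms and stays in [p, 1]
  set.seed(31)
  bg <- paste0("g", 1:60)
  tm <- data.frame(
    gene_id = sample(bg, 120, replace = TRUE),
    term_id = sample(paste0("T", 1:8), 120, replace = TRUE),
    stringsAsFactors = FALSE
  )
  res <- enrich_terms(sample(bg, 15), bg, tm)
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_true(all(res$p_adj <= 1))
  expect_equal(res$p_adj, bh_hand(res$p), tolerance = 1e-12)
})
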