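call_df <- function(sample, scaffold, start, end, kind) {
  data.frame(sample_id = sample, scaffold = scaffold, start = start,
             end = end, kind = kind, stringsAsFactors = FALSE)
}

test_that("chained overlaps merge into one CNVR with distinct-sample support", {
  calls <- call_df(c("s1", "s2", "s3", "s4"), "sc",
                   c(1000, 4000, 8500, 2000), c(5000, 9000, 12000, 3000),
                   "loss")
  r <- merge_calls(calls, min_support = 4)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 1000)
  expect_equal(r$end, 12000)
  expect_equal(r$support, 4L)
  expect_equal(r$type, "loss")

  # a single call forms a support-1 CNVR, removed at the default threshold
  single <- call_df("s1", "sc", 1000, 5000, "gain")
  expect_equal(nrow(merge_calls(single, min_support = 4)), 0L)
  r1 <- merge_calls(single, min_support = 1)
  expect_equal(r1[, c("start", "end", "support")],
               data.frame(start = 1000, end = 5000, support = 1L))

  # two calls from ONE sample count once for support
  dup <- call_df(c("s1", "s1", "s2"), "sc", c(100, 600, 400),
                 c(700, 1200, 800), "gain")
  r2 <- merge_calls(dup, min_support = 1)
  expect_equal(r2$support, 2L)
  expect_equal(r2$n_calls, 3L)

  # half-open abutment does not merge
  ab <- call_df(c("s1", "s2", "s3", "s4", "s5", "s6", "s7", "s8"),
                "sc", c(0, 500, 0, 500, 0, 500, 0, 500),
                c(500, 900, 500, 900, 500, 900, 500, 900), "loss")
  r3 <- merge_calls(ab, min_support = 4)
  expect_equal(nrow(r3), 2L)
  expect_equal(r3$start, c(0, 500))

  expect_error(merge_calls(call_df("s1", "sc", 10, 10, "gain")),
               "input error")
})

test_that("type classification distinguishes gain, loss and both", {
  expect_equal(classify_type(c("gain", "gain")), "gain")
  expect_equal(classify_type(c("gain", "loss")), "both")
  expect_equal(classify_type("loss"), "loss")
  expect_error(classify_type(character(0)), "no contributing calls")
})

test_that("merging matches the connected-component oracle on random sets", {
  set.seed(1234)
  for (rep in 1:500) {
    n <- sample(1:200, 1)
    calls <- data.frame(
      sample_id = paste0("s", sample(1:20, n, replace = TRUE)),
      scaffold = sample(c("A", "B"), n, replace = TRUE),
      start = sample(0:5000, n, replace = TRUE),
      kind = sample(c("gain", "loss"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    calls$end <- calls$start + sample(1:500, n, replace = TRUE)
    got <- merge_calls(calls, min_support = 1)
    want <- merge_oracle(calls)
    expect_equal(got$scaffold, want$scaffold)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$support, want$support)
    expect_equal(got$type, want$type)
  }
})

test_that("merging emitted CNVRs is idempotent and CNVRs are disjoint", {
  set.seed(99)
  n <- 150
  calls <- data.frame(
    sample_id = paste0("s", sample(1:10, n, replace = TRUE)),
    scaffold = "sc",
    start = sample(0:20000, n, replace = TRUE),
    kind = "loss", stringsAsFactors = FALSE
  )
  calls$end <- calls$start + sample(200:2000, n, replace = TRUE)
  r <- merge_calls(calls, min_support = 1)
  # disjoint
  expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  # idempotent: re-merging the CNVR intervals reproduces them
  again <- merge_calls(data.frame(sample_id = "x", scaffold = r$scaffold,
                                  start = r$start, end = r$end,
                                  kind = "loss", stringsAsFactors = FALSE),
                       min_support = 1)
  expect_equal(again$start, r$start)
  expect_equal(again$end, r$end)
  # every contributing call lies inside its CNVR
  contrib <- attr(r, "contributing")
  m <- match(contrib$cnvr_id, r$id)
  expect_true(all(calls$start[contrib$call_row] >= r$start[m] &
                    calls$end[contrib$call_row] <= r$end[m]))
})

test_that("the CN matrix is depth-derived for carriers and non-carriers", {
  lay <- make_layout(200)
  # noiseless diploid and a homozygous-deletion carrier over one region
  t_dip <- make_track(rep(6.7, 200), sample_id = "dip")
  depth_del <- rep(6.7, 200); depth_del[41:60] <- 0
  t_del <- make_track(depth_del, sample_id = "del")
  cnvrs <- data.frame(id = "cnvr_1", scaffold = "s1", start = 20000,
                      end = 30000, type = "loss", support = 2L,
                      stringsAsFactors = FALSE)
  m <- build_cn_matrix(cnvrs, list(dip = t_dip, del = t_del))
  expect_equal(m["cnvr_1", "dip"], 2, tolerance = 1e-12)
  # the deletion carrier's effective depth is slightly below 6.7, so the
  # region value is exactly 0 but the diploid one is exactly 2
  expect_equal(m["cnvr_1", "del"], 0)

  # planted CN=4 carrier at 6.7x over 10 kb lands within 4 +/- 0.5
  set.seed(5)
  ok <- 0L
  for (i in 1:20) {
    d <- rpois(2000, 6.7); d[1001:1020] <- rpois(20, 13.4)
    t4 <- make_track(d, sample_id = "amp")
    m4 <- build_cn_matrix(
      data.frame(id = "r", scaffold = "s1", start = 500000, end = 510000,
                 stringsAsFactors = FALSE),
      list(amp = t4))
    ok <- ok + (abs(m4["r", "amp"] - 4) <= 0.5)
  }
  expect_gte(ok, 17L)

  # uncovered region errors with the sample name
  bad <- data.frame(id = "r", scaffold = "s1", start = 99000, end = 101000,
                    stringsAsFactors = FALSE)
  expect_error(build_cn_matrix(bad, list(dip = t_dip)), "coverage error")
})
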