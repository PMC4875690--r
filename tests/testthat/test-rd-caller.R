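test_that("GC correction equalizes class means and preserves the global mean", {
  # all bins in one GC class: corrected == raw
  lay1 <- make_layout(300, gc = 0.45)
  tr1 <- make_track(rpois(300, 7), corrected = FALSE)
  out1 <- gc_correct(tr1, lay1, min_bins = 10)
  expect_equal(out1$corrected_depth, out1$raw_depth)

  # two equal-sized classes with means 10 and 20 -> both corrected to 15
  lay2 <- make_layout(400)
  lay2$gc$s1 <- rep(c(0.35, 0.55), each = 200)
  tr2 <- make_track(rep(c(10, 20), each = 200), corrected = FALSE)
  out2 <- gc_correct(tr2, lay2, min_bins = 10)
  expect_equal(unique(out2$corrected_depth), 15)

  # global mean preserved when every class is corrected
  lay3 <- make_layout(600)
  set.seed(1)
  lay3$gc$s1 <- rep(c(0.30, 0.45, 0.60), each = 200)
  tr3 <- make_track(rpois(600, 8) * rep(c(0.8, 1.0, 1.2), each = 200),
                    corrected = FALSE)
  out3 <- gc_correct(tr3, lay3, min_bins = 10)
  expect_equal(mean(out3$corrected_depth), mean(tr3$raw_depth),
               tolerance = 1e-9)

  # small classes fall back to no correction
  lay4 <- make_layout(120)
  lay4$gc$s1 <- c(rep(0.45, 110), rep(0.70, 10))
  tr4 <- make_track(c(rpois(110, 7), rpois(10, 3)), corrected = FALSE)
  out4 <- gc_correct(tr4, lay4, min_bins = 100)
  expect_equal(out4$corrected_depth[111:120], tr4$raw_depth[111:120])

  expect_error(gc_correct(make_track(rep(0, 50), corrected = FALSE),
                          make_layout(50)),
               "degenerate")
})

test_that("segmentation recovers a noiseless step exactly", {
  # oracle: exhaustive 2-breakpoint search minimizing within-segment variance
  rd <- c(rep(6.7, 40), rep(3.35, 20), rep(6.7, 40))
  best <- c(NA, NA); best_ss <- Inf
  for (b1 in 1:98) for (b2 in (b1 + 1):99) {
    ss <- sum((rd[1:b1] - mean(rd[1:b1]))^2) +
      sum((rd[(b1 + 1):b2] - mean(rd[(b1 + 1):b2]))^2) +
      sum((rd[(b2 + 1):100] - mean(rd[(b2 + 1):100]))^2)
    if (ss < best_ss) { best_ss <- ss; best <- c(b1, b2) }
  }
  expect_equal(best, c(40, 60))

  seg <- segment_track(make_track(rd))
  expect_equal(nrow(seg), 3L)
  expect_equal(seg$start_bin, c(0L, 40L, 60L))
  expect_equal(seg$end_bin, c(40L, 60L, 100L))
  expect_equal(seg$mean_rd, c(6.7, 3.35, 6.7))
})

test_that("constant and empty tracks segment trivially", {
  seg <- segment_track(make_track(rep(5, 200)))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_bins, 200L)
  # segments tile the scaffold without gaps on a noisy two-scaffold track
  set.seed(2)
  tr <- make_track(c(rpois(300, 7), rpois(200, 7)),
                   scaffold = rep(c("a", "b"), c(300, 200)))
  seg2 <- segment_track(tr)
  for (sc in c("a", "b")) {
    s <- seg2[seg2$scaffold == sc, ]
    expect_equal(s$start_bin[1], 0L)
    expect_equal(s$end_bin[nrow(s)], if (sc == "a") 300L else 200L)
    if (nrow(s) > 1) expect_equal(s$start_bin[-1], s$end_bin[-nrow(s)])
  }
  expect_error(segment_track(make_track(rpois(10, 5), corrected = FALSE)),
               "corrected depths missing")
})

test_that("pure Poisson noise almost always yields a single segment", {
  set.seed(314)
  n_single <- 0L
  for (i in 1:20) {
    seg <- segment_track(make_track(rpois(1000, 7)))
    n_single <- n_single + (nrow(seg) == 1L)
  }
  expect_gte(n_single / 20, 0.95)
})

test_that("call filters apply significance, length, q0 and dosage rules", {
  # background 600 bins at 6.7, plus designed segments
  set.seed(8)
  depth <- c(rpois(600, 6.7),
             rep(3.35, 10),            # A: clear loss, 5 kb
             c(0, 0, 10.05),           # B: mean 3.35 but wildly variable
             rep(3.35, 2),             # C: clear loss but only 1 kb
             rep(10.05, 10),           # D: gain in a high-q0 stretch
             rep(13.4, 6))             # E: clear gain
  q0 <- c(rep(0.02, 615), rep(0.8, 10), rep(0.02, 6))
  tr <- make_track(depth, q0 = q0)
  segments <- data.frame(
    scaffold = "s1",
    start_bin = c(0L, 600L, 610L, 613L, 615L, 625L),
    end_bin = c(600L, 610L, 613L, 615L, 625L, 631L),
    stringsAsFactors = FALSE
  )
  segments$start <- segments$start_bin * 500
  segments$end <- segments$end_bin * 500
  segments$n_bins <- segments$end_bin - segments$start_bin
  cs <- c(0, cumsum(tr$corrected_depth))
  segments$mean_rd <- (cs[segments$end_bin + 1] - cs[segments$start_bin + 1]) /
    segments$n_bins
  st <- genome_stats(tr)
  calls <- call_cnvs(segments, tr, st)
  # retained: A (loss) and E (gain) only
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$kind, c("loss", "gain"))
  expect_equal(calls$start, c(300000, 312500))
  # B fails the t-test (high within-segment variance), C fails the 1.5 kb
  # length rule, D fails the q0 <= 0.5 rule
  expect_true(all(calls$q0_frac <= 0.5))
  expect_true(all(calls$end - calls$start >= 1500))

  # cn normalization: segment mean 3.35 against genome mean ~6.7 gives cn ~1
  expect_equal(calls$cn[1], 2 * segments$mean_rd[2] / st$mean_rd)
  expect_lt(abs(calls$cn[1] - 1), 0.15)

  expect_error(call_cnvs(segments, tr, list(mean_rd = 0)), "degenerate")
})

test_that("diploid background regions report cn near 2", {
  cfg <- sim_config(scaffold_lengths = c(a = 2e6),
                    n_samples = c(wild = 2L, domestic = 2L),
                    n_neutral_events = 0L, n_differentiated_events = 0L,
                    seed = 77L)
  co <- simulate_cohort(cfg)
  tr <- gc_correct(co$tracks[[1]], co$layout)
  st <- genome_stats(tr)
  # 10 kb (20-bin) windows: Poisson noise alone puts a window's cn about
  # 0.17 away from 2 (1 sd), so the +/- 0.3 band holds for most windows
  # and the genome-wide average is tight
  win <- 20
  cn <- vapply(seq(0, 4000 - win, by = win), function(w0)
    2 * mean(tr$corrected_depth[(w0 + 1):(w0 + win)]) / st$mean_rd,
    numeric(1))
  expect_gte(mean(abs(cn - 2) < 0.3), 0.85)
  expect_lt(abs(mean(cn) - 2), 0.05)
})
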