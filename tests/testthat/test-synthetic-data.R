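test_that("generated genome layout has the right bin structure and GC range", {
  cfg <- sim_config(scaffold_lengths = c(a = 1e6), seed = 3L)
  g <- generate_genome(cfg)
  expect_equal(length(g$gc$a), 2000L)  # ceil(1e6 / 500)

  cfg3 <- sim_config(scaffold_lengths = c(a = 2e6, b = 2e6, c = 2e6), seed = 3L)
  g3 <- generate_genome(cfg3)
  expect_equal(sum(lengths(g3$gc)), 12000L)
  expect_true(all(unlist(g3$gc) >= 0 & unlist(g3$gc) <= 1))

  # non-multiple length rounds up
  g4 <- generate_genome(sim_config(scaffold_lengths = c(a = 1001), seed = 1L))
  expect_equal(length(g4$gc$a), 3L)

  expect_error(sim_config(scaffold_lengths = c(a = 0)), "positive")
  expect_error(sim_config(bin_size = 0), "positive")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(scaffold_lengths = c(a = 5e5, b = 5e5),
                    n_samples = c(wild = 3L, domestic = 3L),
                    n_neutral_events = 5L, n_differentiated_events = 2L,
                    seed = 17L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$layout, co2$layout)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$tracks, co2$tracks)
})

test_that("planted truth respects frequencies, disjointness and scaffolds", {
  cfg0 <- sim_config(n_neutral_events = 0L, n_differentiated_events = 0L,
                     n_samples = c(wild = 3L, domestic = 3L), seed = 5L)
  lay0 <- generate_genome(cfg0)
  t0 <- plant_truth(lay0, cfg0)
  expect_equal(nrow(t0$events), 0L)
  expect_equal(nrow(t0$cn), 0L)

  # fixed difference: freq 1 in one population, 0 in the other
  cfg1 <- sim_config(scaffold_lengths = c(a = 1e6),
                     n_samples = c(wild = 5L, domestic = 5L),
                     n_neutral_events = 0L, n_differentiated_events = 1L,
                     diff_freq = c(1, 0), seed = 5L)
  lay1 <- generate_genome(cfg1)
  t1 <- plant_truth(lay1, cfg1)
  hi_pop <- if (t1$events$freq_wild[1] == 1) "wild" else "domestic"
  hi <- t1$samples$sample_id[t1$samples$population == hi_pop]
  lo <- t1$samples$sample_id[t1$samples$population != hi_pop]
  expect_true(all(t1$cn[1, hi] != 2L))
  expect_true(all(t1$cn[1, lo] == 2L))

  # 50 events on a 10 Mb genome: pairwise disjoint by sweep over sorted starts
  cfg50 <- sim_config(n_neutral_events = 40L, n_differentiated_events = 10L,
                      seed = 23L)
  lay50 <- generate_genome(cfg50)
  t50 <- plant_truth(lay50, cfg50)
  expect_equal(nrow(t50$events), 50L)
  for (sc in unique(t50$events$scaffold)) {
    e <- t50$events[t50$events$scaffold == sc, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
    # no event straddles the scaffold end
    len <- lay50$scaffolds$length[lay50$scaffolds$name == sc]
    expect_true(all(e$end <= len & e$start >= 0))
  }
  # carrier CN conventions
  gains <- t50$events$kind == "gain"
  expect_true(all(t50$cn[gains, ][t50$cn[gains, ] != 2L] %in% 3:6))
  expect_true(all(t50$cn[!gains, ][t50$cn[!gains, ] != 2L] %in% 0:1))
})

test_that("simulated depth follows the Poisson dosage model", {
  cfg <- sim_config(scaffold_lengths = c(a = 2e6),
                    n_samples = c(wild = 2L, domestic = 2L),
                    n_neutral_events = 1L, n_differentiated_events = 0L,
                    neutral_freq = 1, seed = 9L,
                    gc_bias = list(peak = 0.45, strength = 0, floor = 1))
  lay <- generate_genome(cfg)
  tr <- plant_truth(lay, cfg)
  s <- tr$samples$sample_id[1]
  track <- simulate_sample_depth(lay, tr, s, cfg)

  expect_true(all(track$q0_frac >= 0 & track$q0_frac <= 1))

  # bins inside a CN=0 event have depth exactly 0
  ev <- tr$events[1, ]
  if (tr$cn[1, s] == 0L) {
    inside <- track$bin_start >= ev$start & track$bin_end <= ev$end
    expect_true(all(track$raw_depth[inside] == 0))
  }

  # with gc_bias == 1, the CN=2 background mean is within 3 SE of mean_depth
  outside <- !(track$bin_start < ev$end & track$bin_end > ev$start)
  m <- mean(track$raw_depth[outside])
  se <- sqrt(cfg$mean_depth / sum(outside))
  expect_lt(abs(m - cfg$mean_depth), 3 * se)

  expect_error(simulate_sample_depth(lay, tr, "nope", cfg), "unknown sample")
})

test_that("genome-wide depth conservation holds under GC bias", {
  cfg <- sim_config(scaffold_lengths = c(a = 2e6),
                    n_samples = c(wild = 2L, domestic = 2L),
                    n_neutral_events = 0L, n_differentiated_events = 0L,
                    seed = 31L)
  lay <- generate_genome(cfg)
  tr <- plant_truth(lay, cfg)
  track <- simulate_sample_depth(lay, tr, tr$samples$sample_id[1], cfg)
  expected <- cfg$mean_depth *
    mean(popcnv:::gc_bias_curve(lay$gc$a, cfg$gc_bias))
  se <- sqrt(expected / nrow(track))
  expect_lt(abs(mean(track$raw_depth) - expected), 4 * se)
})

test_that("repeat regions mark elevated q0 and are avoided by truth events", {
  cfg <- sim_config(scaffold_lengths = c(a = 2e6), repeat_frac = 0.05,
                    n_samples = c(wild = 2L, domestic = 2L),
                    n_neutral_events = 10L, n_differentiated_events = 0L,
                    seed = 13L)
  lay <- generate_genome(cfg)
  reps <- simulate_repeat_regions(lay, cfg)
  expect_gt(nrow(reps), 0)
  expect_true(all(reps$end > reps$start))
  tr <- plant_truth(lay, cfg, repeats = reps)
  track <- simulate_sample_depth(lay, tr, tr$samples$sample_id[1], cfg,
                                 repeats = reps)
  in_rep <- rep(FALSE, nrow(track))
  for (j in seq_len(nrow(reps))) {
    in_rep <- in_rep | (track$bin_start >= reps$start[j] &
                          track$bin_end <= reps$end[j])
  }
  expect_true(all(track$q0_frac[in_rep] == cfg$q0_repeat))
  expect_true(all(track$q0_frac[!in_rep] == cfg$q0_background))
  # events avoid repeats
  for (i in seq_len(nrow(tr$events))) {
    e <- tr$events[i, ]
    r <- reps[reps$scaffold == e$scaffold, ]
    expect_false(any(e$start < r$end & e$end > r$start))
  }
})
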