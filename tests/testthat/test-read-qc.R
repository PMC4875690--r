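phred_string <- function(scores) intToUtf8(scores + 33L)

test_that("single-read rules match hand-traced expectations", {
  # 100 bases with 10 N -> N-fraction discard (>= 10%)
  seq_n <- paste0(strrep("A", 90), strrep("N", 10))
  r <- qc_read(seq_n, phred_string(rep(30, 100)))
  expect_equal(r$action, "discard")
  expect_equal(r$reason, "n_fraction")

  # clean read passes untouched
  r2 <- qc_read(strrep("A", 100), phred_string(rep(30, 100)))
  expect_equal(r2$action, "keep")
  expect_equal(nchar(r2$sequence), 100L)
  expect_equal(r2$bases_trimmed, 0L)

  # 60-base read, Phred <= 13 at 0-based positions 10-12: trimmed to 10,
  # then discarded (10 < 45)
  q <- rep(30, 60); q[11:13] <- 10
  r3 <- qc_read(strrep("A", 60), phred_string(q))
  expect_equal(r3$action, "discard")
  expect_equal(r3$reason, "short")

  # same trim on a long read keeps the 5' prefix
  q4 <- rep(30, 100); q4[51:53] <- 13
  r4 <- qc_read(strrep("A", 100), phred_string(q4))
  expect_equal(r4$action, "keep")
  expect_equal(nchar(r4$sequence), 50L)
  expect_equal(r4$bases_trimmed, 50L)

  # > 65% of bases at Phred <= 7 -> low-quality discard (strict >); the
  # low bases are scattered (no run of 3) so the trim rule stays out of play
  q5 <- c(rep(c(7, 7, 30), 33)[1:99], 7)   # 66 of 100 low
  expect_equal(qc_read(strrep("A", 100), phred_string(q5))$reason,
               "low_quality")
  q6 <- c(rep(c(7, 7, 30), 32), c(7, 30, 30, 30))  # exactly 65 of 100: kept
  r6 <- qc_read(strrep("A", 100), phred_string(q6))
  expect_equal(r6$action, "keep")
  expect_equal(nchar(r6$sequence), 100L)

  # mismatched lengths are a format error
  expect_error(qc_read("ACGT", phred_string(rep(30, 3))), "format error")
})

test_that("adapter rule needs >10 aligned bases with at most 2 mismatches", {
  adapter <- "AGATCGGAAGAGC"
  base <- strrep("T", 60)
  # embed 11 exact adapter bases -> discard
  with_hit <- paste0(strrep("T", 20), substr(adapter, 1, 11), strrep("T", 29))
  r <- qc_read(with_hit, phred_string(rep(30, 60)), adapters = adapter)
  expect_equal(r$reason, "adapter")
  # 10 exact bases still hit: the surrounding 11-base window carries only
  # one mismatch, within the 2 allowed
  with10 <- paste0(strrep("T", 20), substr(adapter, 1, 10), strrep("T", 30))
  expect_equal(qc_read(with10, phred_string(rep(30, 60)),
                       adapters = adapter)$reason, "adapter")
  # 8 exact bases surrounded by non-matching sequence: every 11-base
  # window has at least 3 mismatches -> no hit
  with8 <- paste0(strrep("T", 20), substr(adapter, 1, 8), strrep("T", 32))
  expect_equal(qc_read(with8, phred_string(rep(30, 60)),
                       adapters = adapter)$action, "keep")
  # adapter hanging off the read start still matches 11 aligned bases
  hang <- paste0(substr(adapter, 3, 13), strrep("T", 49))
  expect_equal(qc_read(hang, phred_string(rep(30, 60)),
                       adapters = adapter)$reason, "adapter")
})

test_that("qc is idempotent and report counts are conserved", {
  set.seed(42)
  n <- 30
  reads <- data.frame(
    id = paste0("r", seq_len(n)),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = ""),
      character(1)),
    quality = vapply(seq_len(n), function(i)
      phred_string(sample(c(2, 7, 13, 20, 30, 38), 80, replace = TRUE,
                          prob = c(1, 1, 2, 3, 6, 6))),
      character(1)),
    stringsAsFactors = FALSE
  )
  res <- qc_reads(reads, adapters = "AGATCGGAAGAGC")
  rp <- res$report
  expect_equal(rp$n_kept + rp$discard_n_fraction + rp$discard_low_quality +
                 rp$discard_adapter + rp$discard_short, rp$n_input)
  # idempotence: cleaning the clean output changes nothing
  res2 <- qc_reads(res$reads, adapters = "AGATCGGAAGAGC")
  expect_identical(res2$reads, res$reads)
  expect_equal(res2$report$n_kept, nrow(res$reads))
  expect_equal(res2$report$bases_trimmed, 0L)
})

test_that("duplicate pairs are removed by exact mate-sequence identity", {
  r1 <- data.frame(id = c("a", "b", "c", "d", "e"),
                   sequence = c("ACGT", "ACGT", "ACGT", "TTTT", "ACGA"),
                   stringsAsFactors = FALSE)
  r2 <- data.frame(id = c("a", "b", "c", "d", "e"),
                   sequence = c("GGGG", "GGGG", "GGGA", "CCCC", "GGGG"),
                   stringsAsFactors = FALSE)
  dd <- deduplicate_pairs(r1, r2)
  # (ACGT,GGGG) duplicated once; (ACGT,GGGA), (TTTT,CCCC), (ACGA,GGGG) unique
  expect_equal(dd$report$n_kept_pairs, 4L)
  expect_equal(dd$report$n_duplicate_pairs, 1L)
  expect_equal(dd$reads1$id, c("a", "c", "d", "e"))

  # 5 copies of one pair + 3 unique pairs -> 4 kept
  r1b <- data.frame(id = paste0("p", 1:8),
                    sequence = c(rep("AAAA", 5), "CCCC", "GGGG", "TTTT"),
                    stringsAsFactors = FALSE)
  r2b <- data.frame(id = paste0("p", 1:8),
                    sequence = c(rep("TTTT", 5), "AAAA", "AAAA", "AAAA"),
                    stringsAsFactors = FALSE)
  expect_equal(deduplicate_pairs(r1b, r2b)$report$n_kept_pairs, 4L)

  # orphan mate
  expect_error(deduplicate_pairs(r1, r2[1:4, ]), "pairing error")
})

test_that("FASTQ round trip preserves reads and qualities", {
  reads <- data.frame(id = c("x1", "x2"),
                      sequence = c("ACGTACGTAC", "GGGTTTAAAC"),
                      quality = c("IIIIIIIIII", "!!IIII##II"),
                      stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$quality, reads$quality)
  expect_equal(back$id, reads$id)
})
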