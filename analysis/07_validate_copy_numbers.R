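#!/usr/bin/env Rscript
# Stage 7: validation math on the called copy numbers. (a) qPCR-style
# delta-delta-Ct quantification against a diploid reference locus for a
# random panel of recovered calls, gated at cv% < 0.25; (b) high-depth
# (30x) re-sequencing of three samples, asking what share of their
# original 6.7x calls an overlapping high-depth call confirms.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "common.R"))

cohort <- study_cohort()
calls <- read.table(file.path(RESULTS, "calls.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
rec <- evaluate_recovery(calls, cohort$truth, cohort$layout)

set.seed(STUDY_SEED + 8000L)
panel <- rec$pairs[rec$pairs$recovered, ]
panel <- panel[sample.int(nrow(panel), min(32L, nrow(panel))), ]
rows <- list()
for (j in seq_len(nrow(panel))) {
  vp <- panel[j, ]
  called <- calls[calls$sample_id == vp$sample_id &
                    calls$scaffold == vp$scaffold &
                    calls$start < vp$end & calls$end > vp$start, ][1, ]
  if (vp$true_cn == 0) {
    cn_qpcr <- 0
    ok <- called$cn < 0.5
  } else {
    ct_ref <- 22
    ct_target <- ct_ref - log2(vp$true_cn / 2) + rnorm(1, 0, 0.1)
    cn_qpcr <- ddct_copy_number(ct_target, ct_ref, 22, 22)
    ok <- cv_concordance(called$cn, cn_qpcr)$acceptable
  }
  rows[[j]] <- data.frame(sample_id = vp$sample_id, event_id = vp$event_id,
                          true_cn = vp$true_cn, called_cn = called$cn,
                          qpcr_cn = cn_qpcr, concordant = ok)
}
val <- do.call(rbind, rows)
write.table(val, file.path(RESULTS, "qpcr_validation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("qPCR-style validation: %d/%d calls concordant (%.0f%%)",
                sum(val$concordant), nrow(val),
                100 * mean(val$concordant)))

cfg30 <- study_config()
cfg30$mean_depth <- 30
hd_samples <- cohort$truth$samples$sample_id[c(1L, 2L, 16L)]
hd_calls <- do.call(rbind, lapply(hd_samples, function(s) {
  tr <- simulate_sample_depth(cohort$layout, cohort$truth, s, cfg30,
                              repeats = cohort$repeats)
  call_sample(tr, cohort$layout)$calls
}))
prim <- calls[calls$sample_id %in% hd_samples, ]
cr <- concordance_report(prim, hd_calls, cv_max = 0.25)
message(sprintf("high-depth support: %d/%d original calls confirmed at 30x (%.0f%%)",
                cr$n_supported, cr$n_primary,
                100 * cr$supported_fraction))
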