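#!/usr/bin/env Rscript
# Stage 6: association between CNVRs and segmental duplications — the
# direct-overlap share of large (>15 kb) CNVRs, the 5 Mb flanked variant,
# and a random-placement permutation test (lengths preserved, placement
# uniform per scaffold, +1-corrected empirical p).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "common.R"))

cnvrs <- read.table(file.path(RESULTS, "cnvr.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
sds <- read_bed(file.path(COHORT_DIR, "sd.bed"))
layout <- generate_genome(study_config())

direct <- overlap_fraction(cnvrs, sds, layout, min_len = 15000, flank = 0)
flanked <- overlap_fraction(cnvrs, sds, layout, min_len = 15000, flank = 5e6)
pt <- permutation_test(cnvrs, sds, layout, n_perm = 999L,
                       seed = STUDY_SEED + 7000L, min_len = 0)

out <- list(direct_gt15kb = direct, flanked_5mb = flanked,
            observed = pt$observed, null_mean = pt$null_mean,
            null_sd = pt$null_sd, n_perm = pt$n_perm, p = pt$p)
jsonlite::write_json(out, file.path(RESULTS, "sd_assoc.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf("%.0f%% of >15 kb CNVRs directly overlap an SD (%.0f%% within 5 Mb flanks)",
                100 * direct, 100 * flanked))
message(sprintf("permutation test (fraction statistic, %d perms): observed %.3f vs null %.3f +/- %.3f, p = %.3g",
                pt$n_perm, pt$observed, pt$null_mean, pt$null_sd, pt$p))
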