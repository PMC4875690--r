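#!/usr/bin/env Rscript
# Stage 3: merge the per-sample calls into cross-sample CNV regions
# (connected components of >= 1 bp overlap), drop CNVRs supported by fewer
# than 4 distinct samples, and build the CNVR x sample copy-number matrix
# from depth (so non-calling samples contribute their real dosage).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "common.R"))

calls <- read.table(file.path(RESULTS, "calls.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
cnvrs_all <- merge_calls(calls, min_support = 1L)
cnvrs <- merge_calls(calls, min_support = 4L)

cohort <- study_cohort()
tracks <- corrected_tracks(cohort)
cn_mat <- build_cn_matrix(cnvrs, tracks)
write_cnvrs(cnvrs, file.path(RESULTS, "cnvr"), cn_matrix = cn_mat)

genome_bp <- sum(cohort$layout$scaffolds$length)
message(sprintf("merged %d calls into %d raw regions; %d CNVRs pass the >= 4-sample support filter (%d gain / %d loss / %d both)",
                nrow(calls), nrow(cnvrs_all), nrow(cnvrs),
                sum(cnvrs$type == "gain"), sum(cnvrs$type == "loss"),
                sum(cnvrs$type == "both")))
message(sprintf("CNVRs span %.1f kb = %.1f%% of the %d Mb genome; mean length %.1f kb",
                sum(cnvrs$end - cnvrs$start) / 1e3,
                100 * sum(cnvrs$end - cnvrs$start) / genome_bp,
                round(genome_bp / 1e6),
                mean(cnvrs$end - cnvrs$start) / 1e3))
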