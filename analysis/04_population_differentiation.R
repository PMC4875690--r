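#!/usr/bin/env Rscript
# Stage 4: scan the CN matrix for population-differentiated CNVRs with
# V_ST = (V_T - V_S)/V_T and the Student's t-test, selecting regions in
# the top 5% of V_ST with t-test p < 0.05 (the dual criterion).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "common.R"))

cn_mat <- read_cn_matrix(file.path(RESULTS, "cnvr.cn.tsv"))
samples <- read_sample_table(file.path(COHORT_DIR, "truth.samples.tsv"))
assignment <- setNames(samples$population, samples$sample_id)

res <- select_differentiated(cn_mat, assignment, top_frac = 0.05,
                             alpha = 0.05)
write.table(res[order(-res$v_st), ], file.path(RESULTS, "vst.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("V_ST threshold (95th pct of defined values): %.3f; %d of %d CNVRs selected as wild-vs-domestic differentiated",
                attr(res, "v_st_threshold"), sum(res$selected), nrow(res)))
sel <- res[res$selected, ]
for (i in seq_len(nrow(sel))) {
  message(sprintf("  %s  V_ST = %.3f  t-test p = %.2g",
                  sel$cnvr_id[i], sel$v_st[i], sel$t_p[i]))
}
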