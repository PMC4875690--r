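#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort — a two-population resequencing panel
# (15 wild + 15 domestic) over a 10 Mb multi-scaffold genome at 6.7x, with
# 40 neutral and 10 population-differentiated CNV events planted (CN 0-6),
# GC-biased coverage and high-q0 repeat regions — and write every input the
# downstream stages consume.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "common.R"))

cfg <- study_config()
print(cfg)
cohort <- study_cohort()

for (s in names(cohort$tracks)) {
  write_depth_track(cohort$tracks[[s]],
                    file.path(COHORT_DIR, paste0(s, ".depth.tsv")))
}
write_truth(cohort$truth, file.path(COHORT_DIR, "truth"))

gm <- simulate_gene_models(cohort$layout, cfg, n_genes = 400L,
                           truth = cohort$truth)
write_gene_models(gm$genes, file.path(COHORT_DIR, "genes.gff3"),
                  terms = gm$terms)
sds <- simulate_sd_intervals(cohort$layout, cfg, n_sd = 120L,
                             truth = cohort$truth)
popcnv:::write_bed(sds, file.path(COHORT_DIR, "sd.bed"))

ev <- cohort$truth$events
message(sprintf(
  "simulated %d samples; planted %d events (%d gain / %d loss, %d differentiated), %d genes, %d SD intervals",
  length(cohort$tracks), nrow(ev), sum(ev$kind == "gain"),
  sum(ev$kind == "loss"), sum(ev$class == "differentiated"),
  nrow(gm$genes), nrow(sds)))
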