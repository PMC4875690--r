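#!/usr/bin/env Rscript
# Stage 8: windowed copy-number profiles behind the heatmaps — for the
# most differentiated CNVR, the ratio of each 5 kb window's mean corrected
# depth to each sample's effective depth (and its copy-number scale),
# rendered with samples grouped by population.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "common.R"))

cnvrs <- read.table(file.path(RESULTS, "cnvr.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
vst_tab <- read.table(file.path(RESULTS, "vst.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
pick_id <- vst_tab$cnvr_id[which.max(vst_tab$v_st)]
pick <- cnvrs[cnvrs$id == pick_id, ]

cohort <- study_cohort()
tracks <- corrected_tracks(cohort)
lens <- setNames(cohort$layout$scaffolds$length,
                 cohort$layout$scaffolds$name)
bs <- cohort$layout$bin_size
pad <- 20 * bs
start <- max(0, (pick$start - pad) %/% bs * bs)
end <- min(lens[[pick$scaffold]], pick$end + pad)

pr <- profile_region(tracks, pick$scaffold, start, end, window_size = 5000)
write.table(data.frame(sample = rownames(pr$cn), pr$cn, check.names = FALSE),
            file.path(RESULTS, "heatmap_profile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
groups <- setNames(cohort$truth$samples$population,
                   cohort$truth$samples$sample_id)
render_heatmap(pr, file.path(RESULTS, "heatmap.png"), groups = groups)

pop_means <- tapply(rowMeans(pr$cn), groups[rownames(pr$cn)], mean)
message(sprintf("profiled %s (%s:%d-%d) in %d windows of 5 kb",
                pick_id, pick$scaffold, start, end, ncol(pr$cn)))
message(sprintf("mean CN by population over the region: %s",
                paste(names(pop_means), round(pop_means, 2),
                      sep = " = ", collapse = ", ")))
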