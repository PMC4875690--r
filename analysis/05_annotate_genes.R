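#!/usr/bin/env Rscript
# Stage 5: gene content of the CNVRs (a gene counts when CNVRs cover more
# than half of it) and functional-term enrichment of those genes by the
# upper-tail hypergeometric test with Benjamini-Hochberg FDR control.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "common.R"))

genes <- read_gene_models(file.path(COHORT_DIR, "genes.gff3"))
terms <- read.table(file.path(COHORT_DIR, "genes.gff3.terms.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
cnvrs <- read.table(file.path(RESULTS, "cnvr.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

hits <- genes_in_cnvrs(genes, cnvrs)
write.table(hits, file.path(RESULTS, "cnvr_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
enr <- enrich_terms(unique(hits$gene_id), genes$gene_id, terms,
                    alpha = 0.05)
write.table(enr, file.path(RESULTS, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d of %d genes are >50%% covered by CNVRs (in %d CNVRs)",
                length(unique(hits$gene_id)), nrow(genes),
                length(unique(hits$cnvr_id))))
sig <- enr[enr$significant, ]
message(sprintf("%d of %d terms enriched at FDR 0.05%s", nrow(sig),
                nrow(enr),
                if (nrow(sig)) paste0(": ",
                  paste(sprintf("%s (p_adj %.2g)", sig$term_id, sig$p_adj),
                        collapse = ", ")) else ""))
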