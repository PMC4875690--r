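# Shared setup for the numbered analysis scripts: one seeded study
# configuration (30 samples, 10 Mb, 50 planted events at 6.7x) and the
# output locations. Every script is re-runnable on its own; the cohort is
# reconstructed deterministically from the seed where depth tracks are
# needed in memory.

suppressMessages(library(popcnv))

STUDY_SEED <- 1L
RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohort")

study_config <- function() sim_config(seed = STUDY_SEED)

study_cohort <- function() simulate_cohort(study_config())

corrected_tracks <- function(cohort) {
  lapply(cohort$tracks, gc_correct, layout = cohort$layout)
}

dir.create(COHORT_DIR, recursive = TRUE, showWarnings = FALSE)
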