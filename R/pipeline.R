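#' Default pipeline configuration
#'
#' @return named list of all pipeline parameters with their defaults; see
#'   [run_pipeline()] for the stage each governs.
#' @export
default_pipeline_config <- function() {
  list(
    out_dir = "popcnv_run",
    seed = 1L,
    # simulate
    n_scaffolds = 3L,
    scaffold_length = 1e6,
    bin_size = 500L,
    n_samples = c(wild = 8L, domestic = 8L),
    mean_depth = 6.7,
    n_neutral_events = 16L,
    n_differentiated_events = 4L,
    n_genes = 120L,
    n_sd = 60L,
    # call
    bandwidths = c(2L, 4L, 8L, 16L, 32L),
    alpha = 0.05,
    min_length = 1500,
    max_q0 = 0.5,
    # merge
    min_support = 4L,
    # diff
    top_frac = 0.05,
    t_alpha = 0.05,
    # annotate
    min_gene_fraction = 0.5,
    enrich_alpha = 0.05,
    # sdassoc
    n_perm = 200L,
    flank = 0,
    sd_min_len = 0,
    # heatmap
    window_size = 5000,
    heatmap = TRUE
  )
}

validate_pipeline_config <- function(config) {
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  checks <- list(
    n_scaffolds = cfg$n_scaffolds >= 1,
    scaffold_length = cfg$scaffold_length > 0,
    bin_size = cfg$bin_size > 0,
    mean_depth = cfg$mean_depth > 0,
    alpha = cfg$alpha > 0 && cfg$alpha <= 1,
    min_length = cfg$min_length >= 0,
    max_q0 = cfg$max_q0 >= 0 && cfg$max_q0 <= 1,
    min_support = cfg$min_support >= 1,
    top_frac = cfg$top_frac > 0 && cfg$top_frac < 1,
    n_perm = cfg$n_perm >= 1,
    window_size = cfg$window_size %% cfg$bin_size == 0
  )
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad) > 0) {
    stop("config error: invalid value for field: ", paste(bad, collapse = ", "))
  }
  if (is.list(cfg$n_samples)) cfg$n_samples <- unlist(cfg$n_samples)
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

md5_of <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> call -> merge -> diff -> annotate -> sdassoc ->
#' heatmap, writing every stage's outputs as plain text under
#' `config$out_dir` and a JSON run manifest with per-stage output
#' checksums. All randomness derives from `config$seed` by fixed offsets,
#' so the same config reproduces identical text outputs and checksums
#' (image files are presentational and excluded from checksumming).
#'
#' @param config a named list overriding [default_pipeline_config()], or a
#'   path to a YAML file with the same fields.
#' @return the run manifest (list), invisibly; stage results are also
#'   returned in its `results` element.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(artifact = "popcnv",
                   version = as.character(utils::packageVersion("popcnv")),
                   config = cfg, started = format(Sys.time()), stages = list())

  # -- simulate ---------------------------------------------------------
  scfg <- sim_config(
    scaffold_lengths = stats::setNames(rep(cfg$scaffold_length, cfg$n_scaffolds),
                                       paste0("scaffold_", seq_len(cfg$n_scaffolds))),
    bin_size = cfg$bin_size, n_samples = cfg$n_samples,
    mean_depth = cfg$mean_depth,
    n_neutral_events = cfg$n_neutral_events,
    n_differentiated_events = cfg$n_differentiated_events,
    seed = cfg$seed
  )
  cohort <- simulate_cohort(scfg)
  gm <- simulate_gene_models(cohort$layout, scfg, n_genes = cfg$n_genes,
                             truth = cohort$truth)
  sds <- simulate_sd_intervals(cohort$layout, scfg, n_sd = cfg$n_sd,
                               truth = cohort$truth)
  sim_dir <- file.path(cfg$out_dir, "simulate")
  dir.create(sim_dir, showWarnings = FALSE)
  for (s in names(cohort$tracks)) {
    write_depth_track(cohort$tracks[[s]],
                      file.path(sim_dir, paste0(s, ".depth.tsv")))
  }
  write_truth(cohort$truth, file.path(sim_dir, "truth"))
  write_gene_models(gm$genes, file.path(sim_dir, "genes.gff3"),
                    terms = gm$terms)
  write_bed(sds, file.path(sim_dir, "sd.bed"))
  sim_files <- list.files(sim_dir, full.names = TRUE)
  stage_log("simulate", length(cohort$tracks), " tracks, ",
            nrow(cohort$truth$events), " truth events, ",
            nrow(gm$genes), " genes, ", nrow(sds), " SDs")
  manifest$stages$simulate <- list(outputs = md5_of(sim_files),
                                   n_samples = length(cohort$tracks),
                                   n_events = nrow(cohort$truth$events))

  # -- call -------------------------------------------------------------
  call_dir <- file.path(cfg$out_dir, "call")
  dir.create(call_dir, showWarnings = FALSE)
  all_calls <- list()
  tracks_corr <- list()
  for (s in names(cohort$tracks)) {
    res <- call_sample(cohort$tracks[[s]], cohort$layout,
                       bandwidths = cfg$bandwidths, alpha = cfg$alpha,
                       min_length = cfg$min_length, max_q0 = cfg$max_q0)
    tracks_corr[[s]] <- res$track
    all_calls[[s]] <- res$calls
    write_calls(res$calls, file.path(call_dir, s))
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  stage_log("call", nrow(calls), " calls across ", length(tracks_corr),
            " samples")
  manifest$stages$call <- list(
    outputs = md5_of(list.files(call_dir, full.names = TRUE,
                                pattern = "\\.tsv$")),
    n_calls = nrow(calls))

  # -- merge ------------------------------------------------------------
  cnvrs <- merge_calls(calls, min_support = cfg$min_support)
  cn_mat <- if (nrow(cnvrs) > 0) {
    build_cn_matrix(cnvrs, tracks_corr)
  } else {
    matrix(numeric(), 0, length(tracks_corr),
           dimnames = list(NULL, names(tracks_corr)))
  }
  write_cnvrs(cnvrs, file.path(cfg$out_dir, "cnvr"), cn_matrix = cn_mat)
  stage_log("merge", nrow(cnvrs), " CNVRs (support >= ", cfg$min_support, ")")
  manifest$stages$merge <- list(
    outputs = md5_of(file.path(cfg$out_dir,
                               c("cnvr.tsv", "cnvr.cn.tsv"))),
    n_cnvrs = nrow(cnvrs))

  # -- diff -------------------------------------------------------------
  assignment <- stats::setNames(cohort$truth$samples$population,
                                cohort$truth$samples$sample_id)
  diffres <- NULL
  if (nrow(cnvrs) >= 2) {
    diffres <- select_differentiated(cn_mat, assignment,
                                     top_frac = cfg$top_frac,
                                     alpha = cfg$t_alpha)
    utils::write.table(diffres, file.path(cfg$out_dir, "vst.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log("diff", sum(diffres$selected), " of ", nrow(diffres),
              " CNVRs selected as population-differentiated")
  } else {
    stage_log("diff", "skipped: fewer than 2 CNVRs")
  }
  manifest$stages$diff <- list(
    outputs = md5_of(file.path(cfg$out_dir, "vst.tsv")),
    n_selected = if (is.null(diffres)) 0L else sum(diffres$selected))

  # -- annotate ---------------------------------------------------------
  gene_hits <- genes_in_cnvrs(gm$genes, cnvrs, layout = cohort$layout,
                              min_fraction = cfg$min_gene_fraction)
  enrich <- enrich_terms(unique(gene_hits$gene_id), gm$genes$gene_id,
                         gm$terms, alpha = cfg$enrich_alpha)
  utils::write.table(gene_hits, file.path(cfg$out_dir, "cnvr_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enrich, file.path(cfg$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("annotate", length(unique(gene_hits$gene_id)),
            " genes >50% covered; ", sum(enrich$significant),
            " enriched terms")
  manifest$stages$annotate <- list(
    outputs = md5_of(file.path(cfg$out_dir,
                               c("cnvr_genes.tsv", "enrichment.tsv"))),
    n_genes = length(unique(gene_hits$gene_id)),
    n_enriched_terms = sum(enrich$significant))

  # -- sdassoc ----------------------------------------------------------
  perm <- NULL
  if (nrow(cnvrs) > 0) {
    perm <- permutation_test(cnvrs, sds, cohort$layout,
                             n_perm = cfg$n_perm, seed = cfg$seed + 7000L,
                             flank = cfg$flank, min_len = cfg$sd_min_len)
    jsonlite::write_json(perm[c("observed", "null_mean", "null_sd",
                                "n_perm", "p", "statistic")],
                         file.path(cfg$out_dir, "sd_assoc.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_log("sdassoc", "observed ", signif(perm$observed, 3),
              " vs null ", signif(perm$null_mean, 3), ", p = ",
              signif(perm$p, 3))
  }
  manifest$stages$sdassoc <- list(
    outputs = md5_of(file.path(cfg$out_dir, "sd_assoc.json")),
    p = if (is.null(perm)) NA else perm$p)

  # -- heatmap ----------------------------------------------------------
  profile <- NULL
  if (isTRUE(cfg$heatmap) && nrow(cnvrs) > 0) {
    # profile the most differentiated CNVR (or the best-supported one)
    pick <- if (!is.null(diffres) && any(diffres$defined)) {
      cnvrs[which.max(diffres$v_st), ]
    } else {
      cnvrs[which.max(cnvrs$support), ]
    }
    bs <- cfg$bin_size
    pad <- 10 * bs
    lens <- scaffold_lengths(cohort$layout)
    p_start <- max(0, (pick$start - pad) %/% bs * bs)
    p_end <- min(lens[[pick$scaffold]], pick$end + pad)
    profile <- profile_region(tracks_corr, pick$scaffold, p_start, p_end,
                              window_size = cfg$window_size)
    utils::write.table(
      data.frame(sample = rownames(profile$cn), profile$cn,
                 check.names = FALSE),
      file.path(cfg$out_dir, "heatmap_profile.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    render_heatmap(profile, file.path(cfg$out_dir, "heatmap.png"),
                   groups = assignment)
    stage_log("heatmap", "profiled ", pick$scaffold, ":", p_start, "-",
              p_end, " in ", ncol(profile$cn), " windows")
  }
  manifest$stages$heatmap <- list(
    outputs = md5_of(file.path(cfg$out_dir, "heatmap_profile.tsv")))

  manifest$finished <- format(Sys.time())
  manifest$results <- list(cohort = cohort, calls = calls, cnvrs = cnvrs,
                           cn_matrix = cn_mat, diff = diffres,
                           gene_hits = gene_hits, enrichment = enrich,
                           sd_assoc = perm, profile = profile)
  json <- manifest[setdiff(names(manifest), "results")]
  jsonlite::write_json(json, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
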