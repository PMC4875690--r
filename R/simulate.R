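#' Generate a synthetic genome layout with a smooth per-bin GC track
#'
#' Scaffold names/lengths come from the config; per-bin GC fraction is drawn
#' from a smoothed (moving-average filtered) Gaussian process so that GC
#' varies slowly along each scaffold, as it does in real genomes. The number
#' of GC bins per scaffold is `ceiling(length / bin_size)`.
#'
#' @param config a [sim_config()].
#' @return an object of class `genome_layout`: list with `scaffolds`
#'   (data.frame `name`, `length`), `bin_size`, and `gc` (named list of
#'   per-bin GC fractions in `[0, 1]`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    gc <- lapply(config$scaffold_lengths, function(len) {
      n <- as.integer(ceiling(len / config$bin_size))
      raw <- stats::rnorm(n + 100L)
      sm <- stats::filter(raw, rep(1 / 51, 51), sides = 2, circular = TRUE)
      sm <- as.numeric(sm)[seq_len(n)]
      g <- 0.42 + 0.25 * sm
      pmin(pmax(g, 0.25), 0.65)
    })
  })
  structure(
    list(
      scaffolds = data.frame(name = names(config$scaffold_lengths),
                             length = as.numeric(config$scaffold_lengths),
                             stringsAsFactors = FALSE),
      bin_size = config$bin_size,
      gc = gc
    ),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$scaffolds), "scaffolds,",
      format(sum(x$scaffolds$length), big.mark = ","), "bp, bin",
      x$bin_size, "bp\n")
  invisible(x)
}

n_bins_for <- function(layout, scaffold) {
  len <- layout$scaffolds$length[match(scaffold, layout$scaffolds$name)]
  as.integer(ceiling(len / layout$bin_size))
}

#' Simulate repeat (high multi-mapping) regions
#'
#' Places non-overlapping bin-aligned intervals until `repeat_frac` of the
#' genome is covered; bins inside these regions receive elevated q0 in
#' [simulate_sample_depth()], emulating repetitive sequence where reads map
#' to multiple locations.
#'
#' @param layout a `genome_layout`.
#' @param config a [sim_config()].
#' @return data.frame with `scaffold`, `start`, `end` (0-based half-open bp).
#' @export
simulate_repeat_regions <- function(layout, config) {
  stopifnot(inherits(layout, "genome_layout"), inherits(config, "sim_config"))
  target <- config$repeat_frac * sum(layout$scaffolds$length)
  out <- list()
  if (target <= 0) {
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  bs <- layout$bin_size
  withr::with_seed(config$seed + 2L, {
    placed_bp <- 0
    occupied <- lapply(layout$scaffolds$name, function(s) cbind(numeric(0), numeric(0)))
    names(occupied) <- layout$scaffolds$name
    tries <- 0L
    while (placed_bp < target && tries < 10000L) {
      tries <- tries + 1L
      sc_i <- sample.int(nrow(layout$scaffolds), 1L,
                         prob = layout$scaffolds$length)
      sc <- layout$scaffolds$name[sc_i]
      len <- round(stats::runif(1, 5000, 20000) / bs) * bs
      max_start <- layout$scaffolds$length[sc_i] - len
      if (max_start < 0) next
      start <- floor(stats::runif(1, 0, max_start / bs + 1)) * bs
      end <- start + len
      occ <- occupied[[sc]]
      if (nrow(occ) > 0 && any(start < occ[, 2] & end > occ[, 1])) next
      occupied[[sc]] <- rbind(occ, c(start, end))
      out[[length(out) + 1L]] <- data.frame(scaffold = sc, start = start,
                                            end = end, stringsAsFactors = FALSE)
      placed_bp <- placed_bp + len
    }
  })
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$start), , drop = FALSE]
}

#' Plant a population-structured CNV truth set
#'
#' Places non-overlapping gain/loss events on the genome and assigns carrier
#' status per sample by Bernoulli draws at the event's population
#' frequencies. Neutral events share one carrier frequency across both
#' populations; differentiated events use two frequencies separated by a
#' configured margin (direction randomized per event). Carrier copy numbers
#' are drawn uniformly from {0, 1} for losses and {3, 4, 5, 6} for gains;
#' non-carriers are CN 2 everywhere. Event boundaries are snapped to bin
#' edges and events avoid `repeats` and each other (with a small gap) so
#' that each planted event is an isolated, unambiguous truth interval.
#'
#' @param layout a `genome_layout`.
#' @param config a [sim_config()].
#' @param repeats optional repeat-region data.frame to avoid
#'   (from [simulate_repeat_regions()]).
#' @return object of class `cnv_truth`: list with `events` (data.frame
#'   `event_id`, `scaffold`, `start`, `end`, `kind`, `freq_<pop>` columns),
#'   `cn` (integer matrix events x samples), and `samples` (data.frame
#'   `sample_id`, `population`, `altitude_class`).
#' @export
plant_truth <- function(layout, config, repeats = NULL) {
  stopifnot(inherits(layout, "genome_layout"), inherits(config, "sim_config"))
  pops <- names(config$n_samples)
  samples <- data.frame(
    sample_id = unlist(lapply(pops, function(p)
      sprintf("%s_%02d", p, seq_len(config$n_samples[[p]])))),
    population = rep(pops, times = config$n_samples),
    stringsAsFactors = FALSE
  )
  # altitude class: a secondary grouping of the second population, mirroring
  # a high/low-altitude contrast within the domestic group
  samples$altitude_class <- "none"
  second <- samples$population == pops[2]
  samples$altitude_class[second] <-
    rep(c("high", "low"), length.out = sum(second))

  n_events <- config$n_neutral_events + config$n_differentiated_events
  empty_events <- data.frame(
    event_id = character(), scaffold = character(), start = numeric(),
    end = numeric(), kind = character(), stringsAsFactors = FALSE
  )
  empty_events[[paste0("freq_", pops[1])]] <- numeric()
  empty_events[[paste0("freq_", pops[2])]] <- numeric()
  if (n_events == 0L) {
    return(structure(list(events = empty_events,
                          cn = matrix(integer(), 0, nrow(samples),
                                      dimnames = list(NULL, samples$sample_id)),
                          samples = samples),
                     class = "cnv_truth"))
  }

  bs <- layout$bin_size
  gap <- config$event_gap_bins * bs
  withr::with_seed(config$seed + 3L, {
    occupied <- lapply(layout$scaffolds$name, function(s) {
      if (is.null(repeats)) return(cbind(numeric(0), numeric(0)))
      r <- repeats[repeats$scaffold == s, , drop = FALSE]
      cbind(r$start, r$end)
    })
    names(occupied) <- layout$scaffolds$name

    ev <- vector("list", n_events)
    for (i in seq_len(n_events)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        sc_i <- sample.int(nrow(layout$scaffolds), 1L,
                           prob = layout$scaffolds$length)
        sc <- layout$scaffolds$name[sc_i]
        len <- stats::rlnorm(1, config$event_len_meanlog, config$event_len_sdlog)
        len <- min(max(len, config$event_len_min), config$event_len_max)
        len <- round(len / bs) * bs
        max_start <- layout$scaffolds$length[sc_i] - len
        if (max_start < 0) next
        start <- floor(stats::runif(1, 0, max_start / bs + 1)) * bs
        end <- start + len
        occ <- occupied[[sc]]
        if (nrow(occ) > 0 && any(start - gap < occ[, 2] & end + gap > occ[, 1])) next
        occupied[[sc]] <- rbind(occ, c(start, end))
        ev[[i]] <- data.frame(scaffold = sc, start = start, end = end,
                              stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place event ", i,
             " without overlap after 1000 retries (placement error)")
      }
    }
    events <- do.call(rbind, ev)
    events$kind <- sample(c("gain", "loss"), n_events, replace = TRUE)
    is_diff <- c(rep(FALSE, config$n_neutral_events),
                 rep(TRUE, config$n_differentiated_events))
    f1 <- ifelse(is_diff, NA_real_, config$neutral_freq)
    f2 <- f1
    if (any(is_diff)) {
      hi_first <- sample(c(TRUE, FALSE), sum(is_diff), replace = TRUE)
      f1[is_diff] <- ifelse(hi_first, config$diff_freq[1], config$diff_freq[2])
      f2[is_diff] <- ifelse(hi_first, config$diff_freq[2], config$diff_freq[1])
    }
    events[[paste0("freq_", pops[1])]] <- f1
    events[[paste0("freq_", pops[2])]] <- f2
    events$class <- ifelse(is_diff, "differentiated", "neutral")
    events$event_id <- sprintf("ev_%03d", seq_len(n_events))
    events <- events[, c("event_id", "scaffold", "start", "end", "kind",
                         "class", paste0("freq_", pops))]

    cn <- matrix(2L, n_events, nrow(samples),
                 dimnames = list(events$event_id, samples$sample_id))
    for (i in seq_len(n_events)) {
      for (p in pops) {
        idx <- which(samples$population == p)
        freq <- events[[paste0("freq_", p)]][i]
        carrier <- stats::rbinom(length(idx), 1L, freq) == 1L
        if (any(carrier)) {
          pool <- if (events$kind[i] == "gain") 3:6 else 0:1
          cn[i, idx[carrier]] <- sample(pool, sum(carrier), replace = TRUE)
        }
      }
    }
  })
  structure(list(events = events, cn = cn, samples = samples),
            class = "cnv_truth")
}

#' @export
print.cnv_truth <- function(x, ...) {
  cat("cnv_truth:", nrow(x$events), "events (",
      sum(x$events$kind == "gain"), "gain /", sum(x$events$kind == "loss"),
      "loss ),", nrow(x$samples), "samples\n")
  invisible(x)
}

# Per-bin copy number of one sample over one scaffold.
sample_bin_cn <- function(layout, truth, sample_id, scaffold) {
  nb <- n_bins_for(layout, scaffold)
  cn <- rep(2, nb)
  if (nrow(truth$events) == 0L) return(cn)
  ev <- truth$events[truth$events$scaffold == scaffold, , drop = FALSE]
  if (nrow(ev) == 0L) return(cn)
  bs <- layout$bin_size
  for (i in seq_len(nrow(ev))) {
    s_cn <- truth$cn[ev$event_id[i], sample_id]
    if (s_cn == 2L) next
    # bins fully inside the event (events are bin-aligned, so this is exact)
    b0 <- ev$start[i] %/% bs
    b1 <- ceiling(ev$end[i] / bs)
    cn[(b0 + 1L):b1] <- s_cn
  }
  cn
}

#' Simulate one sample's binned depth track
#'
#' Per-bin read counts are Poisson with rate
#' `mean_depth * (CN / 2) * gc_bias(GC_bin)` (scaled down for a partial last
#' bin); bins inside repeat regions get elevated q0 (`q0_repeat`), all
#' others `q0_background`. Deterministic given the config seed and the
#' sample's position in the sample table.
#'
#' @param layout a `genome_layout`.
#' @param truth a `cnv_truth` from [plant_truth()].
#' @param sample_id one sample present in `truth$samples`.
#' @param config a [sim_config()].
#' @param repeats optional repeat-region data.frame.
#' @return a `depth_track`: data.frame with `scaffold`, `bin_start`,
#'   `bin_end`, `raw_depth`, `corrected_depth` (NA until [gc_correct()]),
#'   `q0_frac`; attributes `sample_id` and `bin_size`.
#' @export
simulate_sample_depth <- function(layout, truth, sample_id, config,
                                  repeats = NULL) {
  stopifnot(inherits(layout, "genome_layout"), inherits(truth, "cnv_truth"),
            inherits(config, "sim_config"))
  s_idx <- match(sample_id, truth$samples$sample_id)
  if (is.na(s_idx)) stop("unknown sample: ", sample_id)
  bs <- layout$bin_size
  per_scaffold <- vector("list", nrow(layout$scaffolds))
  withr::with_seed(config$seed + 1000L + s_idx, {
    for (k in seq_len(nrow(layout$scaffolds))) {
      sc <- layout$scaffolds$name[k]
      len <- layout$scaffolds$length[k]
      nb <- n_bins_for(layout, sc)
      bin_start <- (seq_len(nb) - 1) * bs
      bin_end <- pmin(bin_start + bs, len)
      width_frac <- (bin_end - bin_start) / bs
      cn <- sample_bin_cn(layout, truth, sample_id, sc)
      rate <- config$mean_depth * (cn / 2) *
        gc_bias_curve(layout$gc[[sc]], config$gc_bias) * width_frac
      depth <- stats::rpois(nb, rate)
      q0 <- rep(config$q0_background, nb)
      if (!is.null(repeats)) {
        rr <- repeats[repeats$scaffold == sc, , drop = FALSE]
        if (nrow(rr) > 0) {
          for (j in seq_len(nrow(rr))) {
            inside <- bin_start >= rr$start[j] & bin_end <= rr$end[j]
            q0[inside] <- config$q0_repeat
          }
        }
      }
      per_scaffold[[k]] <- data.frame(
        scaffold = sc, bin_start = bin_start, bin_end = bin_end,
        raw_depth = depth, corrected_depth = NA_real_, q0_frac = q0,
        stringsAsFactors = FALSE
      )
    }
  })
  track <- do.call(rbind, per_scaffold)
  attr(track, "sample_id") <- sample_id
  attr(track, "bin_size") <- bs
  class(track) <- c("depth_track", "data.frame")
  track
}

#' Simulate a full cohort: genome, repeats, truth, and all depth tracks
#'
#' Convenience wrapper running [generate_genome()],
#' [simulate_repeat_regions()], [plant_truth()] and
#' [simulate_sample_depth()] for every sample.
#'
#' @param config a [sim_config()].
#' @return list with `layout`, `repeats`, `truth`, and `tracks` (named list
#'   of `depth_track`s, one per sample).
#' @export
simulate_cohort <- function(config) {
  layout <- generate_genome(config)
  repeats <- simulate_repeat_regions(layout, config)
  truth <- plant_truth(layout, config, repeats = repeats)
  tracks <- lapply(truth$samples$sample_id, function(s)
    simulate_sample_depth(layout, truth, s, config, repeats = repeats))
  names(tracks) <- truth$samples$sample_id
  list(layout = layout, repeats = repeats, truth = truth, tracks = tracks)
}

#' Simulate gene models for annotation fixtures
#'
#' Random non-overlapping genes with synthetic functional term labels. When
#' a truth set is supplied, one designated term is preferentially attached
#' to genes overlapping planted events, so that term-enrichment analysis of
#' CNV genes has a planted positive.
#'
#' @param layout a `genome_layout`.
#' @param config a [sim_config()] (seed source).
#' @param n_genes number of genes to place.
#' @param truth optional `cnv_truth` used to bias term assignment.
#' @param enriched_term term id attached preferentially to event-overlapping
#'   genes.
#' @return list with `genes` (data.frame `gene_id`, `scaffold`, `start`,
#'   `end`) and `terms` (data.frame `gene_id`, `term_id`).
#' @export
simulate_gene_models <- function(layout, config, n_genes = 300L,
                                 truth = NULL, enriched_term = "T001") {
  stopifnot(inherits(layout, "genome_layout"))
  out <- vector("list", n_genes)
  withr::with_seed(config$seed + 4L, {
    occupied <- lapply(layout$scaffolds$name, function(s) cbind(numeric(0), numeric(0)))
    names(occupied) <- layout$scaffolds$name
    kept <- 0L
    tries <- 0L
    while (kept < n_genes && tries < n_genes * 50L) {
      tries <- tries + 1L
      sc_i <- sample.int(nrow(layout$scaffolds), 1L,
                         prob = layout$scaffolds$length)
      sc <- layout$scaffolds$name[sc_i]
      len <- round(stats::runif(1, 1000, 12000))
      max_start <- layout$scaffolds$length[sc_i] - len
      if (max_start < 0) next
      start <- floor(stats::runif(1, 0, max_start))
      end <- start + len
      occ <- occupied[[sc]]
      if (nrow(occ) > 0 && any(start < occ[, 2] & end > occ[, 1])) next
      occupied[[sc]] <- rbind(occ, c(start, end))
      kept <- kept + 1L
      out[[kept]] <- data.frame(scaffold = sc, start = start, end = end,
                                stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, out[seq_len(kept)])
    genes <- genes[order(genes$scaffold, genes$start), , drop = FALSE]
    genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "scaffold", "start", "end")]

    in_event <- rep(FALSE, nrow(genes))
    if (!is.null(truth) && nrow(truth$events) > 0) {
      g_gr <- gr0(genes$scaffold, genes$start, genes$end)
      e_gr <- gr0(truth$events$scaffold, truth$events$start, truth$events$end)
      in_event <- IRanges::overlapsAny(g_gr, e_gr)
    }
    other_terms <- sprintf("T%03d", 2:20)
    term_rows <- lapply(seq_len(nrow(genes)), function(i) {
      terms <- sample(other_terms, sample(1:2, 1))
      p_enriched <- if (in_event[i]) 0.6 else 0.05
      if (stats::runif(1) < p_enriched) terms <- c(enriched_term, terms)
      data.frame(gene_id = genes$gene_id[i], term_id = terms,
                 stringsAsFactors = FALSE)
    })
  })
  list(genes = genes, terms = do.call(rbind, term_rows))
}

#' Simulate segmental-duplication intervals
#'
#' SDs are CNV-formation hotspots, so a configurable fraction of simulated
#' SDs is placed near planted events (within `near_bp`), the rest uniformly.
#'
#' @param layout a `genome_layout`.
#' @param config a [sim_config()] (seed source).
#' @param n_sd number of SD intervals.
#' @param truth optional `cnv_truth`; when given, `assoc_frac` of SDs are
#'   placed near events.
#' @param assoc_frac fraction of SDs placed near truth events.
#' @param near_bp maximum distance from an event for "near" placements.
#' @return data.frame `scaffold`, `start`, `end` (0-based half-open),
#'   normalized (sorted, overlaps unioned).
#' @export
simulate_sd_intervals <- function(layout, config, n_sd = 100L, truth = NULL,
                                  assoc_frac = 0.5, near_bp = 2e4) {
  stopifnot(inherits(layout, "genome_layout"))
  lens <- scaffold_lengths(layout)
  withr::with_seed(config$seed + 5L, {
    rows <- vector("list", n_sd)
    for (i in seq_len(n_sd)) {
      len <- round(stats::runif(1, 2000, 50000))
      near <- !is.null(truth) && nrow(truth$events) > 0 &&
        stats::runif(1) < assoc_frac
      if (near) {
        e <- truth$events[sample.int(nrow(truth$events), 1L), ]
        sc <- e$scaffold
        center <- (e$start + e$end) / 2 + stats::runif(1, -near_bp, near_bp)
        start <- max(0, round(center - len / 2))
      } else {
        sc_i <- sample.int(length(lens), 1L, prob = lens)
        sc <- names(lens)[sc_i]
        start <- floor(stats::runif(1, 0, lens[[sc]] - len))
      }
      end <- min(start + len, lens[[sc]])
      if (end - start < 1000) next
      rows[[i]] <- data.frame(scaffold = sc, start = start, end = end,
                              stringsAsFactors = FALSE)
    }
  })
  normalize_intervals(do.call(rbind, rows))
}
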