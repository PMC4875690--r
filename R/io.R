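#' @title Plain-text readers and writers for pipeline artifacts
#' @description Depth tracks, truth sets, sample tables, calls, CNVRs and
#' copy-number matrices travel as TSV/BED/GFF3/JSON so every stage can run
#' standalone. BED and GFF3 go through rtracklayer; coordinates in all
#' data.frames are 0-based half-open (BED convention).
#' @name popcnv_io
NULL

#' Write a depth track as 5-column TSV
#'
#' Columns: sample, scaffold, bin_start, depth, q0_frac.
#'
#' @param track a `depth_track`.
#' @param path output TSV path.
#' @export
write_depth_track <- function(track, path) {
  out <- data.frame(
    sample = attr(track, "sample_id"),
    scaffold = track$scaffold,
    bin_start = track$bin_start,
    depth = track$raw_depth,
    q0_frac = track$q0_frac,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 5-column depth TSV back into a `depth_track`
#'
#' @param path TSV written by [write_depth_track()] (or an external depth
#'   extractor producing the same columns).
#' @param layout a `genome_layout` supplying bin size and scaffold lengths
#'   (for the bin_end of partial last bins).
#' @return a `depth_track`.
#' @export
read_depth_track <- function(path, layout) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  sid <- unique(x$sample)
  if (length(sid) != 1L) stop("depth TSV must contain exactly one sample")
  lens <- scaffold_lengths(layout)
  track <- data.frame(
    scaffold = x$scaffold,
    bin_start = x$bin_start,
    bin_end = pmin(x$bin_start + layout$bin_size, lens[x$scaffold]),
    raw_depth = x$depth,
    corrected_depth = NA_real_,
    q0_frac = x$q0_frac,
    stringsAsFactors = FALSE
  )
  attr(track, "sample_id") <- sid
  attr(track, "bin_size") <- layout$bin_size
  class(track) <- c("depth_track", "data.frame")
  track
}

# intervals data.frame (scaffold, start, end [, name, score]) -> BED file
write_bed <- function(intervals, path, names = NULL, scores = NULL) {
  gr <- gr0(intervals$scaffold, intervals$start, intervals$end)
  if (!is.null(names)) gr$name <- names
  if (!is.null(scores)) gr$score <- scores
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED file.
#' @return data.frame `scaffold`, `start`, `end` (0-based half-open), plus
#'   `name` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- df0(gr)
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' Write the truth set: BED intervals plus a JSON sidecar
#'
#' @param truth a `cnv_truth`.
#' @param prefix output prefix; writes `<prefix>.bed`,
#'   `<prefix>.json` (events, frequencies and the CN matrix) and
#'   `<prefix>.samples.tsv`.
#' @export
write_truth <- function(truth, prefix) {
  bed <- paste0(prefix, ".bed")
  if (nrow(truth$events) > 0) {
    write_bed(truth$events, bed, names = truth$events$event_id)
  } else {
    file.create(bed)
  }
  jsonlite::write_json(
    list(events = truth$events,
         cn = as.data.frame(truth$cn),
         samples = truth$samples),
    paste0(prefix, ".json"), digits = NA
  )
  utils::write.table(truth$samples, paste0(prefix, ".samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a sample table TSV (sample_id, population, ...)
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write CNV calls as BED and full-precision TSV
#'
#' BED name is the call kind, score is `round(100 * cn)`; the TSV keeps
#' p-values and q0.
#'
#' @param calls call data.frame.
#' @param prefix writes `<prefix>.bed` and `<prefix>.tsv`.
#' @export
write_calls <- function(calls, prefix) {
  if (nrow(calls) > 0) {
    write_bed(calls, paste0(prefix, ".bed"), names = calls$kind,
              scores = pmin(round(100 * calls$cn), 1000))
  } else {
    file.create(paste0(prefix, ".bed"))
  }
  utils::write.table(calls, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Write gene models as GFF3 (plus a term-map TSV)
#'
#' @param genes data.frame `gene_id`, `scaffold`, `start`, `end` (0-based
#'   half-open; written as 1-based inclusive GFF3).
#' @param path GFF3 output path.
#' @param terms optional data.frame `gene_id`, `term_id`; written next to
#'   the GFF3 as `<path>.terms.tsv`.
#' @export
write_gene_models <- function(genes, path, terms = NULL) {
  gr <- gr0(genes$scaffold, genes$start, genes$end)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "GFF3")
  if (!is.null(terms)) {
    utils::write.table(terms, paste0(path, ".terms.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' GFF3 is 1-based inclusive on disk; coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @param path GFF3 path.
#' @return data.frame `gene_id`, `scaffold`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  out <- df0(gr)
  out$gene_id <- if (!is.null(gr$ID)) gr$ID else paste0("gene_", seq_along(gr))
  out[, c("gene_id", "scaffold", "start", "end")]
}

#' Write a CNVR table and the CNVR x sample CN matrix
#'
#' @param cnvrs CNVR data.frame from [merge_calls()].
#' @param prefix writes `<prefix>.bed` and `<prefix>.tsv`.
#' @param cn_matrix optional matrix from [build_cn_matrix()]; written as
#'   `<prefix>.cn.tsv` with CNVR ids in the first column.
#' @export
write_cnvrs <- function(cnvrs, prefix, cn_matrix = NULL) {
  if (nrow(cnvrs) > 0) {
    write_bed(cnvrs, paste0(prefix, ".bed"), names = cnvrs$type,
              scores = cnvrs$support)
  } else {
    file.create(paste0(prefix, ".bed"))
  }
  utils::write.table(cnvrs, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cn_matrix)) {
    out <- data.frame(cnvr_id = rownames(cn_matrix), cn_matrix,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, paste0(prefix, ".cn.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a CN matrix TSV written by [write_cnvrs()]
#'
#' @param path `.cn.tsv` path.
#' @return numeric matrix with CNVR-id rownames.
#' @export
read_cn_matrix <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}
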