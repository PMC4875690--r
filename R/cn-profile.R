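#' Windowed copy-number profile of a region across samples
#'
#' For every sample and window, the ratio of the window's mean corrected
#' bin depth to the sample's effective depth (genome-wide mean corrected
#' autosomal depth; median optional). Ratios are reported both on the ratio
#' scale (diploid = 1) and the copy-number scale (2 x ratio, diploid = 2).
#' Windows tile the region left to right; the last window may be shorter.
#'
#' @param tracks named list of corrected `depth_track`s.
#' @param scaffold,start,end the region (0-based half-open bp; `start` must
#'   be bin-aligned).
#' @param window_size window width in bp, a multiple of the bin size
#'   (default 5000; 3000 is the fine-scale variant).
#' @param sex_scaffolds passed to [genome_stats()].
#' @param center effective-depth summary, `"mean"` (default) or
#'   `"median"`.
#' @return object of class `cn_profile`: list with `scaffold`, `start`,
#'   `end`, `window_size`, `windows` (data.frame `start`, `end`), `ratio`
#'   and `cn` (sample x window matrices).
#' @export
profile_region <- function(tracks, scaffold, start, end, window_size = 5000,
                           sex_scaffolds = character(), center = "mean") {
  stopifnot(is.list(tracks), length(tracks) > 0, !is.null(names(tracks)))
  bs <- attr(tracks[[1]], "bin_size")
  if (window_size %% bs != 0 || window_size <= 0) {
    stop("configuration error: window_size must be a positive multiple of the bin size (",
         bs, ")")
  }
  if (start %% bs != 0) stop("start must be bin-aligned")
  if (end <= start) stop("end must be > start")
  w_start <- seq(start, end - 1, by = window_size)
  w_end <- pmin(w_start + window_size, end)
  ratio <- matrix(NA_real_, length(tracks), length(w_start),
                  dimnames = list(names(tracks),
                                  paste0(scaffold, ":", w_start)))
  for (s in names(tracks)) {
    tr <- tracks[[s]]
    if (anyNA(tr$corrected_depth)) {
      stop("corrected depths missing for sample ", s)
    }
    eff <- genome_stats(tr, sex_scaffolds = sex_scaffolds,
                        center = center)$mean_rd
    rows <- which(tr$scaffold == scaffold)
    if (length(rows) == 0L) {
      stop("coverage error: sample ", s, " has no bins on ", scaffold)
    }
    for (j in seq_along(w_start)) {
      b0 <- w_start[j] %/% bs + 1L
      b1 <- as.integer(ceiling(w_end[j] / bs))
      if (b1 > length(rows)) {
        stop("coverage error: sample ", s, " does not cover ", scaffold,
             ":", w_start[j], "-", w_end[j])
      }
      ratio[s, j] <- mean(tr$corrected_depth[rows[b0:b1]]) / eff
    }
  }
  structure(list(scaffold = scaffold, start = start, end = end,
                 window_size = window_size,
                 windows = data.frame(start = w_start, end = w_end),
                 ratio = ratio, cn = 2 * ratio),
            class = "cn_profile")
}

#' Render a copy-number heatmap of a windowed profile
#'
#' Samples as rows (grouped by population when `groups` is given, in group
#' order), windows as columns, no clustering, purely presentational.
#'
#' @param profile a `cn_profile` from [profile_region()].
#' @param out_path output image path (`.png` or `.pdf`).
#' @param groups optional named character vector mapping sample id to group
#'   label; rows are ordered by group.
#' @param scale `"cn"` (default) or `"ratio"`.
#' @return the output path, invisibly; attribute `"row_order"` records the
#'   rendered sample order.
#' @export
render_heatmap <- function(profile, out_path, groups = NULL, scale = "cn") {
  stopifnot(inherits(profile, "cn_profile"))
  mat <- if (scale == "ratio") profile$ratio else profile$cn
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("empty profile")
  ann <- NA
  if (!is.null(groups)) {
    ord <- order(groups[rownames(mat)])
    mat <- mat[ord, , drop = FALSE]
    ann <- data.frame(group = unname(groups[rownames(mat)]),
                      row.names = rownames(mat))
  }
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  # a constant matrix (e.g. an all-diploid region) breaks pheatmap's
  # automatic color breaks; widen them explicitly
  breaks <- if (diff(range(mat)) == 0) {
    seq(mat[1] - 1, mat[1] + 1, length.out = 101)
  } else {
    NA
  }
  pheatmap::pheatmap(
    mat,
    cluster_rows = FALSE, cluster_cols = FALSE,
    annotation_row = if (is.null(groups)) NA else ann,
    breaks = breaks,
    show_colnames = FALSE,
    main = sprintf("%s:%d-%d (%s scale)", profile$scaffold, profile$start,
                   profile$end, scale),
    filename = out_path, silent = TRUE
  )
  out <- invisible(out_path)
  attr(out, "row_order") <- rownames(mat)
  invisible(out)
}
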