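#' Simulation configuration for a synthetic resequencing cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: genome layout,
#' per-bin sequencing depth, GC-bias response, repeat (high-q0) content, the
#' planted CNV truth set, and the master seed. Defaults emulate a
#' low-coverage population resequencing study: two populations, ~6.7 reads
#' expected per 500-bp bin per diploid copy pair, planted events with copy
#' numbers 0--6 and lengths drawn around an 8-kb median.
#'
#' @param scaffold_lengths named integer vector of scaffold lengths (bp).
#' @param bin_size bin width in bp (default 500).
#' @param n_samples named integer vector: samples per population; names are
#'   the population labels (exactly two populations).
#' @param mean_depth expected reads per bin for a diploid (CN = 2) bin with
#'   neutral GC response; the reads-per-bin equivalent of ~6.7x coverage.
#' @param gc_bias list with `peak`, `strength`, `floor`: the GC response is
#'   `max(floor, 1 - strength * (gc - peak)^2)`, a unimodal bump.
#' @param repeat_frac fraction of the genome to cover with simulated
#'   repeat regions (elevated multi-mapping q0).
#' @param q0_repeat,q0_background q0 fraction assigned to bins inside /
#'   outside repeat regions.
#' @param n_neutral_events,n_differentiated_events planted event counts.
#' @param neutral_freq carrier frequency of neutral events (both populations).
#' @param diff_freq length-2 numeric: carrier frequencies of differentiated
#'   events in the high- and low-frequency population.
#' @param event_len_min,event_len_max truncation bounds for event length (bp).
#' @param event_len_meanlog,event_len_sdlog log-normal length parameters
#'   (default median 8 kb).
#' @param event_gap_bins minimum gap between planted events, in bins.
#' @param seed master integer seed; all stages derive child seeds from it by
#'   fixed offsets, so a fixed config reproduces byte-identical outputs.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(scaffold_lengths = stats::setNames(rep(2e6, 5), paste0("scaffold_", 1:5)),
                       bin_size = 500L,
                       n_samples = c(wild = 15L, domestic = 15L),
                       mean_depth = 6.7,
                       gc_bias = list(peak = 0.45, strength = 2, floor = 0.6),
                       repeat_frac = 0.02,
                       q0_repeat = 0.8,
                       q0_background = 0.02,
                       n_neutral_events = 40L,
                       n_differentiated_events = 10L,
                       neutral_freq = 0.3,
                       diff_freq = c(0.95, 0.05),
                       event_len_min = 3000,
                       event_len_max = 1e5,
                       event_len_meanlog = log(8000),
                       event_len_sdlog = 0.7,
                       event_gap_bins = 2L,
                       seed = 1L) {
  if (length(scaffold_lengths) < 1 || is.null(names(scaffold_lengths)) ||
      any(!nzchar(names(scaffold_lengths)))) {
    stop("`scaffold_lengths` must be a named vector with at least one scaffold")
  }
  if (any(scaffold_lengths <= 0)) stop("scaffold lengths must be positive")
  if (bin_size <= 0) stop("`bin_size` must be positive")
  if (length(n_samples) != 2 || is.null(names(n_samples)))
    stop("`n_samples` must be a named length-2 vector (two populations)")
  if (any(n_samples < 0)) stop("sample counts must be >= 0")
  if (mean_depth < 0) stop("`mean_depth` must be >= 0")
  if (repeat_frac < 0 || repeat_frac >= 1) stop("`repeat_frac` must be in [0, 1)")
  if (n_neutral_events < 0 || n_differentiated_events < 0)
    stop("event counts must be >= 0")
  if (neutral_freq < 0 || neutral_freq > 1) stop("`neutral_freq` must be in [0, 1]")
  if (length(diff_freq) != 2 || any(diff_freq < 0 | diff_freq > 1))
    stop("`diff_freq` must be two frequencies in [0, 1]")
  if (event_len_min < bin_size) stop("`event_len_min` must be >= bin_size")
  cfg <- list(
    scaffold_lengths = scaffold_lengths,
    bin_size = as.integer(bin_size),
    n_samples = n_samples,
    mean_depth = mean_depth,
    gc_bias = gc_bias,
    repeat_frac = repeat_frac,
    q0_repeat = q0_repeat,
    q0_background = q0_background,
    n_neutral_events = as.integer(n_neutral_events),
    n_differentiated_events = as.integer(n_differentiated_events),
    neutral_freq = neutral_freq,
    diff_freq = diff_freq,
    event_len_min = event_len_min,
    event_len_max = event_len_max,
    event_len_meanlog = event_len_meanlog,
    event_len_sdlog = event_len_sdlog,
    event_gap_bins = as.integer(event_gap_bins),
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      length(x$scaffold_lengths), "scaffolds,",
      format(sum(x$scaffold_lengths), big.mark = ","), "bp,",
      "bin", x$bin_size, "bp\n")
  cat("  samples:", paste(names(x$n_samples), x$n_samples, sep = "=", collapse = ", "),
      "| mean depth", x$mean_depth, "reads/bin\n")
  cat("  events:", x$n_neutral_events, "neutral +",
      x$n_differentiated_events, "differentiated | seed", x$seed, "\n")
  invisible(x)
}

# GC response curve: unimodal quadratic bump with a floor.
gc_bias_curve <- function(gc, params) {
  pmax(params$floor, 1 - params$strength * (gc - params$peak)^2)
}
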