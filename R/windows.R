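#' Analysis-window configuration
#'
#' A `window_config` collects every named analysis window used by the
#' pipeline, each a half-open interval `[start, end)` in seconds relative to a
#' reference event, paired with a baseline window, plus the smoothing and
#' significance constants shared across analyses.
#'
#' @param windows named list; each element is a list with fields `window`
#'   (numeric length-2, seconds relative to the reference event), `baseline`
#'   (numeric length-2), and `reference` (event column name, e.g.
#'   `"whisker_onset_s"`).
#' @param sigma_s named numeric vector of Gaussian smoothing SDs in seconds.
#' @param thresholds named numeric vector of significance levels.
#' @return an object of class `window_config`.
#' @export
window_config <- function(windows, sigma_s, thresholds) {
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (w$window[2] <= w$window[1])
      stop("window '", nm, "': end must exceed start")
    if (w$baseline[2] <= w$baseline[1])
      stop("window '", nm, "': baseline end must exceed start")
  }
  if (any(sigma_s < 0)) stop("smoothing sigma must be >= 0")
  structure(list(windows = windows, sigma_s = sigma_s,
                 thresholds = thresholds),
            class = "window_config")
}

#' Default analysis windows
#'
#' The default window table, keyed by area and analysis epoch (seconds
#' relative to whisker onset unless stated otherwise):
#' fast sensory windows 0-50 ms for wS1/wS2 (50-ms pre-whisker baseline),
#' 10-90 ms for wM1/wM2, 40-90 ms for tjM1, the 200-1,000-ms delay window
#' for ALM, the 150-350-ms late sensory window for wS1/wS2, and a 0-100-ms
#' early window common to all areas. Each baseline mirrors the duration of
#' its analysis window and ends at the whisker onset. Smoothing defaults are
#' a 10-ms Gaussian SD (5 ms for the high-resolution sensory-latency
#' variant); significance thresholds are 0.025 for per-direction modulation
#' calls, 0.005 for the strict modulated-fraction maps, and 0.05 for
#' responsiveness in the latency analysis.
#'
#' @return a `window_config`.
#' @export
default_window_config <- function() {
  win <- function(a, b, base, ref = "whisker_onset_s")
    list(window = c(a, b), baseline = base, reference = ref)
  windows <- list(
    wS1_fast  = win(0.000, 0.050, c(-0.050, 0)),
    wS2_fast  = win(0.000, 0.050, c(-0.050, 0)),
    early_100 = win(0.000, 0.100, c(-0.100, 0)),
    wM1_early = win(0.010, 0.090, c(-0.080, 0)),
    wM2_early = win(0.010, 0.090, c(-0.080, 0)),
    tjM1_early = win(0.040, 0.090, c(-0.050, 0)),
    ALM_delay = win(0.200, 1.000, c(-0.800, 0)),
    wS1_late  = win(0.150, 0.350, c(-0.200, 0)),
    wS2_late  = win(0.150, 0.350, c(-0.200, 0)),
    latency_200 = win(0.000, 0.200, c(-0.200, 0)),
    latency_100 = win(0.000, 0.100, c(-0.100, 0)),
    baseline_2s = list(window = c(-2, 0), baseline = c(-2, 0),
                       reference = "visual_onset_s")
  )
  window_config(
    windows,
    sigma_s = c(psth = 0.010, latency = 0.010, latency_hires = 0.005),
    thresholds = c(modulation = 0.025, modulation_strict = 0.005,
                   responsive = 0.05, omi = 0.05)
  )
}

#' Look up a named analysis window
#'
#' @param config a `window_config`.
#' @param name window name, e.g. `"wM1_early"`.
#' @return list with `window`, `baseline` (seconds, half-open `[start, end)`)
#'   and `reference`.
#' @export
window_lookup <- function(config, name) {
  stopifnot(inherits(config, "window_config"))
  w <- config$windows[[name]]
  if (is.null(w)) stop("unknown window: '", name, "'")
  w
}

#' Default per-area response window names
#'
#' Maps each cortical area to the analysis window used for its headline
#' evoked-response quantification.
#' @return named character vector.
#' @export
area_window_map <- function() {
  c(wS1 = "wS1_fast", wS2 = "wS2_fast", wM1 = "wM1_early",
    wM2 = "wM2_early", ALM = "ALM_delay", tjM1 = "tjM1_early")
}
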