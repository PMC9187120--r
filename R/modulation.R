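#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate aligned to a reference event, in 1-ms
#' non-overlapping bins, optionally smoothed with a Gaussian kernel. The
#' kernel is truncated at +/- 4 sigma and renormalised to unit area; bin-edge
#' effects are handled by reflective padding so interior spike mass is
#' conserved.
#'
#' @param spike_times spike times (s).
#' @param trials trial data.frame.
#' @param reference trial column holding the alignment event.
#' @param span length-2 window in seconds around the event.
#' @param bin_width_s bin width (s).
#' @param sigma_s Gaussian smoothing SD (s); 0 disables smoothing.
#' @param outcomes optional outcome filter (see [select_trials()]).
#' @return object of class `psth`: list with `bin_centers_s`, `rate_hz`,
#'   `bin_width_s`, `sigma_s`, `n_trials`, `reference`.
#' @export
compute_psth <- function(spike_times, trials, reference = "whisker_onset_s",
                         span = c(-0.5, 0.5), bin_width_s = 0.001,
                         sigma_s = 0.010, outcomes = NULL) {
  if (bin_width_s <= 0) stop("bin_width_s must be > 0")
  trials <- select_trials(trials, outcomes)
  ev <- trials[[reference]]
  ev <- ev[!is.na(ev)]
  if (length(ev) == 0) stop("compute_psth: no trials pass the filter")
  edges <- seq(span[1], span[2], by = bin_width_s)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  for (t0 in ev) {
    rel <- spike_times[spike_times >= t0 + span[1] &
                       spike_times < t0 + edges[nb + 1]] - t0
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, edges,
                                               rightmost.closed = FALSE),
                                  nbins = nb)
  }
  rate <- counts / (length(ev) * bin_width_s)
  if (sigma_s > 0) rate <- .gauss_smooth(rate, sigma_s / bin_width_s)
  structure(list(bin_centers_s = edges[-(nb + 1)] + bin_width_s / 2,
                 rate_hz = rate, bin_width_s = bin_width_s,
                 sigma_s = sigma_s, n_trials = length(ev),
                 reference = reference),
            class = "psth")
}

# Gaussian smoothing with reflective padding; sigma in bins
.gauss_smooth <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(rev(x[seq_len(min(half, n))]), x,
           rev(x[seq.int(max(1, n - half + 1), n)]))
  sm <- stats::filter(pad, k, sides = 2)
  as.numeric(sm[(half + 1):(half + n)])
}

#' Per-trial firing rates in a window
#'
#' One rate (Hz) per selected trial, counting spikes in the half-open window
#' `[start, end)` relative to the reference event.
#'
#' @inheritParams compute_psth
#' @param window length-2 window (s) relative to the event.
#' @return numeric vector, one rate per trial.
#' @export
trial_window_rates <- function(spike_times, trials, window,
                               reference = "whisker_onset_s",
                               outcomes = NULL) {
  trials <- select_trials(trials, outcomes)
  ev <- trials[[reference]]
  ev <- ev[!is.na(ev)]
  if (length(ev) == 0) stop("trial_window_rates: no usable trials")
  dur <- diff(window)
  vapply(ev, function(t0)
    sum(spike_times >= t0 + window[1] & spike_times < t0 + window[2]) / dur,
    0)
}

#' Window-based evoked response of one unit
#'
#' Per-trial delta = rate in the response window minus rate in the baseline
#' window; significance from a paired sign-flip permutation test on the
#' per-trial deltas, assessed one-sidedly in each direction at `threshold`.
#'
#' @inheritParams trial_window_rates
#' @param response_window,baseline_window length-2 windows (s) relative to
#'   the event.
#' @param n_perm,seed permutation-test controls.
#' @param threshold per-direction significance level (default 0.025).
#' @return object of class `evoked_response`: `delta_rate_hz`,
#'   `per_trial_deltas`, `p_value` (two-sided), `p_positive`, `p_negative`,
#'   `direction` in `{"positive", "negative", "none"}`, `n_trials`.
#' @export
evoked_response <- function(spike_times, trials, response_window,
                            baseline_window, reference = "whisker_onset_s",
                            outcomes = NULL, n_perm = 10000, seed = 1,
                            threshold = 0.025) {
  resp <- trial_window_rates(spike_times, trials, response_window,
                             reference, outcomes)
  base <- trial_window_rates(spike_times, trials, baseline_window,
                             reference, outcomes)
  d <- resp - base
  if (all(d == 0)) {
    return(structure(list(delta_rate_hz = 0, per_trial_deltas = d,
                          p_value = 1, p_positive = 1, p_negative = 1,
                          direction = "none", n_trials = length(d)),
                     class = "evoked_response"))
  }
  two <- permutation_test_paired(d, n_perm, seed, "two-sided")
  pos <- permutation_test_paired(d, n_perm, seed, "greater")
  neg <- permutation_test_paired(d, n_perm, seed, "less")
  direction <- if (pos$p_value < threshold) "positive"
               else if (neg$p_value < threshold) "negative" else "none"
  structure(list(delta_rate_hz = mean(d), per_trial_deltas = d,
                 p_value = two$p_value, p_positive = pos$p_value,
                 p_negative = neg$p_value, direction = direction,
                 n_trials = length(d)),
            class = "evoked_response")
}

#' Evoked responses for every unit of a session
#'
#' Applies [evoked_response()] to each unit using its area's default window
#' (see [area_window_map()]), or a fixed named window.
#'
#' @param s a `spike_session`.
#' @param config a `window_config`.
#' @param window_name fixed window name, or NULL to use the per-area map.
#' @param outcomes trial outcome filter (default hit trials).
#' @param n_perm,seed,threshold passed to [evoked_response()].
#' @return data.frame with one row per unit: `unit_id`, `area`, `cell_class`,
#'   `window`, `delta_rate_hz`, `p_value`, `p_positive`, `p_negative`,
#'   `direction`.
#' @export
session_evoked_responses <- function(s, config = default_window_config(),
                                     window_name = NULL, outcomes = "hit",
                                     n_perm = 10000, seed = 1,
                                     threshold = NULL) {
  if (is.null(threshold)) threshold <- config$thresholds[["modulation"]]
  wmap <- area_window_map()
  rows <- lapply(seq_len(nrow(s$units)), function(i) {
    u <- s$units[i, ]
    wn <- if (is.null(window_name)) wmap[[u$area]] else window_name
    w <- window_lookup(config, wn)
    er <- evoked_response(s$spikes[[as.character(u$unit_id)]], s$trials,
                          w$window, w$baseline, w$reference, outcomes,
                          n_perm, seed + i, threshold)
    data.frame(unit_id = u$unit_id, area = u$area,
               cell_class = u$cell_class, window = wn,
               delta_rate_hz = er$delta_rate_hz, p_value = er$p_value,
               p_positive = er$p_positive, p_negative = er$p_negative,
               direction = er$direction)
  })
  do.call(rbind, rows)
}

#' Fractions of positively and negatively modulated units
#'
#' Per area and cell class: the fraction of units whose one-sided
#' permutation p-value falls below `threshold` in each direction. Groups
#' with 5 or fewer units are flagged (`reportable = FALSE`), matching the
#' reporting floor used for modulated-fraction maps.
#'
#' @param responses data.frame from [session_evoked_responses()].
#' @param threshold per-direction significance level.
#' @return data.frame with `area`, `cell_class`, `n`, `n_positive`,
#'   `n_negative`, `frac_positive`, `frac_negative`, `reportable`.
#' @export
modulated_fractions <- function(responses, threshold = 0.025) {
  key <- interaction(responses$area, responses$cell_class, drop = TRUE)
  rows <- lapply(split(responses, key), function(g) {
    np <- sum(g$p_positive < threshold)
    nn <- sum(g$p_negative < threshold)
    n <- nrow(g)
    data.frame(area = g$area[1], cell_class = g$cell_class[1], n = n,
               n_positive = np, n_negative = nn,
               frac_positive = np / n, frac_negative = nn / n,
               reportable = n > 5)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare evoked responses between two groups of units
#'
#' Unpaired permutation test on the per-unit evoked deltas (e.g. Novice
#' versus Expert cohorts for one area and cell class).
#'
#' @param deltas_a,deltas_b numeric vectors of per-unit `delta_rate_hz`.
#' @param n_perm,seed,alternative passed to [permutation_test_unpaired()].
#' @return a `perm_test_result`.
#' @export
compare_groups <- function(deltas_a, deltas_b, n_perm = 10000, seed = 1,
                           alternative = "two-sided") {
  permutation_test_unpaired(deltas_a, deltas_b, n_perm, seed, alternative)
}

#' Contrast one unit's window rates between two outcome subsets
#'
#' Unpaired permutation test on per-trial window rates between two sets of
#' trial outcomes (e.g. correct rejection versus miss).
#'
#' @inheritParams trial_window_rates
#' @param outcomes_a,outcomes_b outcome labels defining the two subsets.
#' @param n_perm,seed permutation controls.
#' @return a `perm_test_result`.
#' @export
outcome_contrast <- function(spike_times, trials, outcomes_a, outcomes_b,
                             window, reference = "auditory_onset_s",
                             n_perm = 10000, seed = 1) {
  ra <- trial_window_rates(spike_times, trials, window, reference,
                           outcomes = outcomes_a)
  rb <- trial_window_rates(spike_times, trials, window, reference,
                           outcomes = outcomes_b)
  if (length(ra) == 1 && length(rb) == 1)
    warning("single trial per subset; exhaustive permutations = 2")
  permutation_test_unpaired(ra, rb, n_perm, seed)
}
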