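#' Per-train light and baseline rates of one unit
#'
#' Rates in the light window (100-500 ms after train onset) and a baseline
#' window of equal duration (-400 to 0 ms before onset), per train and
#' averaged.
#'
#' @param spike_times spike times (s).
#' @param light_onsets light-train onset times (s).
#' @param light_window,baseline_window windows (s) relative to train onset.
#' @return list with `ap_light`, `ap_baseline` (Hz, means), and the
#'   per-train vectors `light_rates`, `baseline_rates`.
#' @export
opto_rates <- function(spike_times, light_onsets,
                       light_window = c(0.100, 0.500),
                       baseline_window = c(-0.400, 0)) {
  if (length(light_onsets) == 0) stop("opto_rates: no light onsets")
  rate_in <- function(win) {
    dur <- diff(win)
    vapply(light_onsets, function(t0)
      sum(spike_times >= t0 + win[1] & spike_times < t0 + win[2]) / dur, 0)
  }
  lr <- rate_in(light_window)
  br <- rate_in(baseline_window)
  list(ap_light = mean(lr), ap_baseline = mean(br),
       light_rates = lr, baseline_rates = br)
}

#' Opto modulation index
#'
#' `OMI = (AP_light - AP_baseline) / (AP_light + AP_baseline)`, in
#' \[-1, 1\]: +1 for units firing only during light, -1 for units fully
#' silenced.
#'
#' @param ap_light,ap_baseline mean rates (Hz) in the light and baseline
#'   windows, or a list from [opto_rates()] as first argument.
#' @return the index; `NA` (with a warning) when both rates are zero.
#' @export
opto_modulation_index <- function(ap_light, ap_baseline = NULL) {
  if (is.list(ap_light)) {
    ap_baseline <- ap_light$ap_baseline
    ap_light <- ap_light$ap_light
  }
  if (ap_light < 0 || ap_baseline < 0) stop("rates must be >= 0")
  if (ap_light + ap_baseline == 0) {
    warning("OMI undefined: both rates are zero")
    return(NA_real_)
  }
  (ap_light - ap_baseline) / (ap_light + ap_baseline)
}

#' Significance of light modulation
#'
#' Paired permutation test on per-train (light - baseline) rate differences.
#'
#' @param rates list from [opto_rates()].
#' @param n_perm,seed permutation controls.
#' @return a `perm_test_result`.
#' @export
omi_significance <- function(rates, n_perm = 10000, seed = 1) {
  if (length(rates$light_rates) < 2)
    stop("omi_significance: need at least 2 trains")
  permutation_test_paired(rates$light_rates - rates$baseline_rates,
                          n_perm, seed, "two-sided")
}

#' Fast light-response metrics (fidelity, latency, jitter)
#'
#' Within the half-open window `[onset, onset + window_ms)` immediately
#' after each light-train onset: fidelity is the percentage of trains with
#' at least one spike; latency is the mean first-spike delay over spiking
#' trains; jitter is the sample SD (n - 1) of those delays. The first 10 ms
#' precede any network effect of sustained stimulation, so these metrics
#' isolate direct opsin-driven responses.
#'
#' @param spike_times spike times (s).
#' @param light_onsets train onset times (s).
#' @param window_ms search window (default 10 ms).
#' @return list with `fidelity_pct`, `latency_ms`, `jitter_ms`,
#'   `n_trains`, `n_spiking`. Latency and jitter are `NA` when no train
#'   contains a spike.
#' @export
fast_response_metrics <- function(spike_times, light_onsets,
                                  window_ms = 10) {
  if (length(light_onsets) == 0)
    stop("fast_response_metrics: no light onsets")
  w <- window_ms / 1000
  first_ms <- vapply(light_onsets, function(t0) {
    hit <- spike_times[spike_times >= t0 & spike_times < t0 + w]
    if (length(hit)) (hit[1] - t0) * 1000 else NA_real_
  }, 0)
  spiking <- first_ms[!is.na(first_ms)]
  fid <- 100 * length(spiking) / length(light_onsets)
  list(fidelity_pct = fid,
       latency_ms = if (length(spiking)) mean(spiking) else NA_real_,
       jitter_ms = if (length(spiking) > 1) stats::sd(spiking)
                   else if (length(spiking) == 1) 0 else NA_real_,
       n_trains = length(light_onsets), n_spiking = length(spiking))
}

#' Opto-tag decision
#'
#' A unit is labelled opto-tagged when all three criteria hold strictly:
#' fidelity above 20%, mean first-spike latency below 4.5 ms, and jitter
#' below 2 ms. Units with zero fidelity (undefined latency/jitter) are not
#' tagged.
#'
#' @param metrics list from [fast_response_metrics()].
#' @param fidelity_min,latency_max,jitter_max thresholds.
#' @return logical.
#' @export
is_optotagged <- function(metrics, fidelity_min = 20, latency_max = 4.5,
                          jitter_max = 2) {
  if (is.na(metrics$latency_ms) || is.na(metrics$jitter_ms)) return(FALSE)
  metrics$fidelity_pct > fidelity_min &&
    metrics$latency_ms < latency_max &&
    metrics$jitter_ms < jitter_max
}

#' Opto-tagging metrics for every unit of a session
#'
#' @param s a `spike_session` with `light_pulses`.
#' @param n_perm,seed permutation controls for the OMI test.
#' @param window_ms fast-response window.
#' @return data.frame with one row per unit: rates, `omi`, `omi_p`,
#'   `fidelity_pct`, `latency_ms`, `jitter_ms`, `tagged`.
#' @export
session_tag_metrics <- function(s, n_perm = 10000, seed = 1,
                                window_ms = 10) {
  if (is.null(s$light_pulses))
    stop("OMI undefined: session has no light pulses")
  rows <- lapply(seq_len(nrow(s$units)), function(i) {
    id <- as.character(s$units$unit_id[i])
    st <- s$spikes[[id]]
    r <- opto_rates(st, s$light_pulses)
    omi <- suppressWarnings(opto_modulation_index(r))
    omi_p <- if (all(r$light_rates == r$baseline_rates)) 1
             else omi_significance(r, n_perm, seed + i)$p_value
    m <- fast_response_metrics(st, s$light_pulses, window_ms)
    data.frame(unit_id = id, area = s$units$area[i],
               cell_class = s$units$cell_class[i],
               ap_light = r$ap_light, ap_baseline = r$ap_baseline,
               omi = omi, omi_p = omi_p,
               fidelity_pct = m$fidelity_pct, latency_ms = m$latency_ms,
               jitter_ms = m$jitter_ms, tagged = is_optotagged(m))
  })
  do.call(rbind, rows)
}
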