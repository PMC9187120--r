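#' Per-trial evoked-response vector for correlation analysis
#'
#' One rate per trial in the area-specific evoked window (5-55 ms after
#' whisker onset for wS1/wS2, 10-90 ms for wM1/wM2). Units whose mean rate
#' in the window is at or below `rate_min` (default 2.5 Hz) are flagged as
#' excluded from the pairwise Pearson analysis.
#'
#' @param spike_times spike times (s).
#' @param trials trial data.frame.
#' @param window length-2 window (s) relative to the reference event.
#' @param reference alignment event.
#' @param outcomes trial filter.
#' @param rate_min inclusion threshold (Hz).
#' @return numeric vector of per-trial rates with attributes `mean_rate_hz`
#'   and `included`.
#' @export
trial_response_vector <- function(spike_times, trials, window,
                                  reference = "whisker_onset_s",
                                  outcomes = NULL, rate_min = 2.5) {
  r <- trial_window_rates(spike_times, trials, window, reference, outcomes)
  attr(r, "mean_rate_hz") <- mean(r)
  attr(r, "included") <- mean(r) > rate_min
  r
}

#' Pearson correlation between two trial-response vectors
#'
#' @param vec_a,vec_b equal-length numeric vectors (>= 3 trials).
#' @return sample Pearson r; `NA` with a warning when either vector is
#'   constant.
#' @export
pairwise_pearson <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b)) stop("vectors must have equal length")
  if (length(vec_a) < 3) stop("need at least 3 trials")
  if (stats::sd(vec_a) == 0 || stats::sd(vec_b) == 0) {
    warning("Pearson undefined: constant response vector")
    return(NA_real_)
  }
  stats::cor(vec_a, vec_b)
}

#' Population-level trial-by-trial Pearson correlation
#'
#' Pearson correlation between the per-trial across-unit mean rates of two
#' simultaneously recorded areas.
#'
#' @param rates_a,rates_b lists of per-trial rate vectors (one element per
#'   unit) for the two areas.
#' @return Pearson r.
#' @export
population_pearson <- function(rates_a, rates_b) {
  if (length(rates_a) == 0 || length(rates_b) == 0)
    stop("population_pearson: one area has no units")
  ma <- rowMeans(do.call(cbind, rates_a))
  mb <- rowMeans(do.call(cbind, rates_b))
  pairwise_pearson(ma, mb)
}

#' Spike time tiling coefficient
#'
#' Rate-insensitive pairwise spike-train correlation:
#' `STTC = 1/2 * ((P_A - T_B)/(1 - P_A*T_B) + (P_B - T_A)/(1 - P_B*T_A))`,
#' where `P_A` is the proportion of spikes of A falling within `dt` of a
#' spike of B (and vice versa) and `T_A` is the proportion of the interval
#' covered by the union of `+/- dt` neighbourhoods of A's spikes (clipped at
#' the interval edges). A half-term whose denominator vanishes is dropped
#' and the value is the mean of the remaining term(s).
#'
#' @param train_a,train_b spike times (s); restricted to `interval`.
#' @param interval length-2 analysis interval (s); the convention here is a
#'   1-second window centred on the whisker stimulus.
#' @param dt coincidence half-width (s), default 0.010.
#' @return list with `value`, `P_A`, `P_B`, `T_A`, `T_B`, `dt_s`,
#'   `interval`. `value` is `NA` (flagged by a warning) when either train is
#'   empty.
#' @export
sttc <- function(train_a, train_b, interval, dt = 0.010) {
  a <- train_a[train_a >= interval[1] & train_a <= interval[2]]
  b <- train_b[train_b >= interval[1] & train_b <= interval[2]]
  if (length(a) == 0 || length(b) == 0) {
    warning("STTC undefined: empty spike train in interval")
    return(list(value = NA_real_, P_A = NA, P_B = NA, T_A = NA, T_B = NA,
                dt_s = dt, interval = interval))
  }
  prop_near <- function(x, y) {
    # fraction of x within dt of some y
    idx <- findInterval(x, y)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(y))
    near <- abs(x - y[lo]) <= dt | abs(x - y[hi]) <= dt
    mean(near)
  }
  tiling <- function(x) {
    st <- pmax(x - dt, interval[1])
    en <- pmin(x + dt, interval[2])
    tot <- 0; cur_s <- st[1]; cur_e <- en[1]
    for (i in seq_along(st)[-1]) {
      if (st[i] <= cur_e) cur_e <- max(cur_e, en[i])
      else { tot <- tot + (cur_e - cur_s); cur_s <- st[i]; cur_e <- en[i] }
    }
    (tot + (cur_e - cur_s)) / diff(interval)
  }
  P_A <- prop_near(a, b); P_B <- prop_near(b, a)
  T_A <- tiling(a); T_B <- tiling(b)
  terms <- c()
  if (1 - P_A * T_B != 0) terms <- c(terms, (P_A - T_B) / (1 - P_A * T_B))
  if (1 - P_B * T_A != 0) terms <- c(terms, (P_B - T_A) / (1 - P_B * T_A))
  val <- if (length(terms)) mean(terms) else NA_real_
  if (is.na(val)) warning("STTC undefined: both terms degenerate")
  list(value = val, P_A = P_A, P_B = P_B, T_A = T_A, T_B = T_B,
       dt_s = dt, interval = interval)
}

#' Bin a unit's spikes by trial for cross-correlogram analysis
#'
#' 1-ms bins over an analysis window around the reference event (default the
#' 1-second window centred on whisker onset). The sparse (trial, bin)
#' representation keeps one row per spike.
#'
#' @inheritParams trial_response_vector
#' @param bin_width_s bin width (s).
#' @return object of class `binned_trial_spikes`: data.frame `spk` with
#'   columns `trial`, `bin` (1-based), plus `n_trials`, `n_bins`,
#'   `bin_width_s`, `lambda` (mean spikes per bin), `rate_hz`.
#' @export
bin_trial_spikes <- function(spike_times, trials, window = c(-0.5, 0.5),
                             reference = "whisker_onset_s",
                             outcomes = NULL, bin_width_s = 0.001) {
  trials <- select_trials(trials, outcomes)
  ev <- trials[[reference]]
  ev <- ev[!is.na(ev)]
  if (length(ev) == 0) stop("bin_trial_spikes: no usable trials")
  n_bins <- as.integer(round(diff(window) / bin_width_s))
  rows <- lapply(seq_along(ev), function(i) {
    rel <- spike_times[spike_times >= ev[i] + window[1] &
                       spike_times < ev[i] + window[2]] - (ev[i] + window[1])
    if (!length(rel)) return(NULL)
    data.frame(trial = i, bin = pmin(n_bins, floor(rel / bin_width_s) + 1L))
  })
  spk <- do.call(rbind, rows)
  if (is.null(spk)) spk <- data.frame(trial = integer(), bin = integer())
  lambda <- nrow(spk) / (length(ev) * n_bins)
  structure(list(spk = spk, n_trials = length(ev), n_bins = n_bins,
                 bin_width_s = bin_width_s, lambda = lambda,
                 rate_hz = lambda / bin_width_s),
            class = "binned_trial_spikes")
}

# coincidence counts per lag between two sparse (trial, bin) tables
.ccg_counts <- function(spk_ref, spk_tgt, max_lag_bins) {
  if (nrow(spk_ref) == 0 || nrow(spk_tgt) == 0)
    return(numeric(2 * max_lag_bins + 1))
  A <- data.table::as.data.table(spk_ref)
  B <- data.table::as.data.table(spk_tgt)
  pairs <- merge(A, B, by = "trial", allow.cartesian = TRUE,
                 suffixes = c("_ref", "_tgt"))
  d <- pairs$bin_tgt - pairs$bin_ref
  d <- d[abs(d) <= max_lag_bins]
  tabulate(d + max_lag_bins + 1L, nbins = 2L * max_lag_bins + 1L)
}

#' Normalized cross-correlogram between two units
#'
#' `CCG(tau) = (1/M) * sum_i sum_t chi1_i(t) chi2_i(t + tau) /
#' (theta(tau) * lambda1 * lambda2)`, where M is the trial count, the chi
#' are the per-trial binned spike trains, `theta(tau) = N - |tau|` bins
#' corrects for the shrinking overlap at larger lags, and the lambda are
#' mean rates in spikes per bin measured within the analysis window, so that
#' independent stationary units give an expected CCG of 1 at every lag.
#' Both units must exceed `rate_min` (default 1 Hz) in the window.
#'
#' @param binned_ref,binned_tgt [bin_trial_spikes()] objects of the
#'   reference and target unit (same trials and window).
#' @param max_lag_s maximum lag (s), default 0.1.
#' @param rate_min inclusion threshold (Hz).
#' @return object of class `ccg_result`: `lags_s`, `ccg_raw`, plus metadata.
#' @export
ccg <- function(binned_ref, binned_tgt, max_lag_s = 0.1, rate_min = 1) {
  stopifnot(binned_ref$n_bins == binned_tgt$n_bins,
            binned_ref$n_trials == binned_tgt$n_trials)
  if (binned_ref$lambda == 0 || binned_tgt$lambda == 0)
    stop("ccg: a unit has no spikes in the analysis window")
  if (binned_ref$rate_hz <= rate_min || binned_tgt$rate_hz <= rate_min)
    warning("unit below the ", rate_min, " Hz inclusion threshold")
  bw <- binned_ref$bin_width_s
  L <- as.integer(round(max_lag_s / bw))
  counts <- .ccg_counts(binned_ref$spk, binned_tgt$spk, L)
  lags_bins <- seq(-L, L)
  theta <- binned_ref$n_bins - abs(lags_bins)
  denom <- theta * binned_ref$lambda * binned_tgt$lambda
  raw <- (counts / binned_ref$n_trials) / denom
  structure(list(lags_s = lags_bins * bw, ccg_raw = raw,
                 ccg_jittered = NULL, ccg_corrected = NULL,
                 n_trials = binned_ref$n_trials, n_bins = binned_ref$n_bins,
                 bin_width_s = bw, max_lag_bins = L,
                 lambda_ref = binned_ref$lambda,
                 lambda_tgt = binned_tgt$lambda),
            class = "ccg_result")
}

#' Jitter-correct a cross-correlogram
#'
#' Removes stimulus-locked and slow (> jitter window) correlations: in each
#' resample the target unit's spikes are exchanged across trials within
#' every 25-ms time slice (each slice keeps its across-trial spike pool, so
#' the trial-averaged PSTH is preserved exactly), the CCG is recomputed, and
#' the mean over resamples is subtracted from the raw CCG. Only the target
#' train is permuted; permuting both would double the resampling variance
#' without changing the expectation.
#'
#' @inheritParams ccg
#' @param jitter_window_s slice width (s), default 0.025.
#' @param n_resamples number of resamples, default 100.
#' @param seed seed.
#' @return a `ccg_result` with `ccg_raw`, `ccg_jittered` and
#'   `ccg_corrected = ccg_raw - ccg_jittered`.
#' @export
jitter_correct <- function(binned_ref, binned_tgt, max_lag_s = 0.1,
                           jitter_window_s = 0.025, n_resamples = 100,
                           seed = 1, rate_min = 1) {
  if (binned_ref$n_trials < 2)
    stop("jitter_correct: need at least 2 trials to permute across")
  res <- ccg(binned_ref, binned_tgt, max_lag_s, rate_min)
  bw <- binned_ref$bin_width_s
  L <- res$max_lag_bins
  M <- binned_ref$n_trials
  slice_bins <- as.integer(round(jitter_window_s / bw))
  tgt <- binned_tgt$spk
  slice <- (tgt$bin - 1L) %/% slice_bins + 1L
  n_slices <- max(1L, as.integer(ceiling(binned_tgt$n_bins / slice_bins)))
  denom <- (binned_ref$n_bins - abs(seq(-L, L))) *
    binned_ref$lambda * binned_tgt$lambda
  set.seed(seed)
  acc <- numeric(2 * L + 1)
  for (r in seq_len(n_resamples)) {
    perms <- matrix(0L, nrow = M, ncol = n_slices)
    for (sl in seq_len(n_slices)) perms[, sl] <- sample.int(M)
    jit <- data.frame(trial = perms[cbind(tgt$trial, slice)], bin = tgt$bin)
    acc <- acc + .ccg_counts(binned_ref$spk, jit, L)
  }
  jittered <- (acc / n_resamples / M) / denom
  res$ccg_jittered <- jittered
  res$ccg_corrected <- res$ccg_raw - jittered
  res$n_resamples <- n_resamples
  res$jitter_window_s <- jitter_window_s
  res
}

#' Detect a directional connection from a corrected cross-correlogram
#'
#' The flank SD is the standard deviation of the jitter-corrected CCG over
#' lags with `|tau|` in the flank range (50-100 ms, both sides pooled). A
#' directional connection from reference to target is detected when the
#' maximum corrected CCG at lags in `(0, 10]` ms exceeds `k` times the flank
#' SD. The zero lag is excluded to preserve directionality.
#'
#' @param ccg_result a `ccg_result` with `ccg_corrected` present (or a
#'   numeric corrected CCG, in which case `lags_s` must be supplied).
#' @param lags_s lag vector when `ccg_result` is numeric.
#' @param detect_max_s upper edge of the detection lag range (s).
#' @param flank_range_s flank lag range (s).
#' @param k threshold multiplier (default 6).
#' @return list with `detected`, `peak_lag_s`, `peak_value`, `flank_sd`,
#'   `threshold`, `degenerate`.
#' @export
detect_connection <- function(ccg_result, lags_s = NULL,
                              detect_max_s = 0.010,
                              flank_range_s = c(0.050, 0.100), k = 6) {
  if (inherits(ccg_result, "ccg_result")) {
    corr <- ccg_result$ccg_corrected
    if (is.null(corr)) stop("detect_connection: run jitter_correct first")
    lags_s <- ccg_result$lags_s
  } else {
    corr <- ccg_result
    if (is.null(lags_s)) stop("detect_connection: lags_s required")
  }
  eps <- 1e-9
  flank <- abs(lags_s) >= flank_range_s[1] - eps &
           abs(lags_s) <= flank_range_s[2] + eps
  det <- lags_s > eps & lags_s <= detect_max_s + eps
  flank_sd <- stats::sd(corr[flank])
  if (!is.finite(flank_sd) || flank_sd == 0) {
    return(list(detected = FALSE, peak_lag_s = NA_real_,
                peak_value = NA_real_, flank_sd = flank_sd,
                threshold = NA_real_, degenerate = TRUE))
  }
  vals <- corr[det]
  peak_i <- which.max(vals)
  list(detected = vals[peak_i] > k * flank_sd,
       peak_lag_s = lags_s[det][peak_i], peak_value = vals[peak_i],
       flank_sd = flank_sd, threshold = k * flank_sd, degenerate = FALSE)
}

#' Pairwise connectivity analysis for a session
#'
#' For each ordered (reference -> target) unit pair across two areas:
#' trial-by-trial Pearson correlation of evoked responses, STTC in the
#' 1-second window centred on the whisker stimulus, and jitter-corrected
#' CCG connection detection.
#'
#' @param s a `spike_session`.
#' @param ref_area,tgt_area area names (sensory reference, motor target).
#' @param config a `window_config`; the Pearson windows follow the
#'   convention 5-55 ms (wS1/wS2) and 10-90 ms (wM1/wM2) after whisker
#'   onset.
#' @param outcomes trial filter for the evoked windows.
#' @param n_resamples,seed jitter-correction controls.
#' @param rate_min_pearson,rate_min_ccg inclusion thresholds (Hz).
#' @return data.frame, one row per pair: `pre_unit`, `post_unit`,
#'   `pearson_r`, `sttc`, `detected`, `peak_lag_ms`, `flank_sd`.
#' @export
session_connectivity <- function(s, ref_area, tgt_area,
                                 config = default_window_config(),
                                 outcomes = NULL, n_resamples = 100,
                                 seed = 1, rate_min_pearson = 2.5,
                                 rate_min_ccg = 1) {
  sens_win <- c(0.005, 0.055)
  mot_win <- c(0.010, 0.090)
  refs <- s$units$unit_id[s$units$area == ref_area &
                          s$units$cell_class == "RS"]
  tgts <- s$units$unit_id[s$units$area == tgt_area]
  if (length(refs) == 0 || length(tgts) == 0)
    stop("session_connectivity: an area has no units")
  binned <- lapply(stats::setNames(nm = as.character(c(refs, tgts))),
                   function(id)
                     bin_trial_spikes(s$spikes[[id]], s$trials,
                                      window = c(-0.5, 0.5),
                                      outcomes = outcomes))
  rows <- list()
  pair_i <- 0L
  for (rid in as.character(refs)) for (tid in as.character(tgts)) {
    pair_i <- pair_i + 1L
    va <- trial_response_vector(s$spikes[[rid]], s$trials, sens_win,
                                outcomes = outcomes,
                                rate_min = rate_min_pearson)
    vb <- trial_response_vector(s$spikes[[tid]], s$trials, mot_win,
                                outcomes = outcomes,
                                rate_min = rate_min_pearson)
    r <- if (attr(va, "included") && attr(vb, "included"))
      suppressWarnings(pairwise_pearson(as.numeric(va), as.numeric(vb)))
    else NA_real_
    stt <- NA_real_
    wt <- s$trials$whisker_onset_s
    wt <- wt[!is.na(wt)]
    if (length(wt)) {
      vals <- vapply(wt, function(w0)
        suppressWarnings(sttc(s$spikes[[rid]], s$spikes[[tid]],
                              interval = c(w0 - 0.5, w0 + 0.5))$value), 0)
      stt <- mean(vals, na.rm = TRUE)
    }
    det <- list(detected = NA, peak_lag_s = NA_real_, flank_sd = NA_real_)
    if (binned[[rid]]$rate_hz > rate_min_ccg &&
        binned[[tid]]$rate_hz > rate_min_ccg) {
      jc <- jitter_correct(binned[[rid]], binned[[tid]],
                           n_resamples = n_resamples,
                           seed = .unit_seed(seed, pair_i))
      det <- detect_connection(jc)
    }
    rows[[pair_i]] <- data.frame(
      pre_unit = rid, post_unit = tid, pearson_r = r, sttc = stt,
      detected = det$detected, peak_lag_ms = det$peak_lag_s * 1000,
      flank_sd = det$flank_sd)
  }
  do.call(rbind, rows)
}
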