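#' Simulation configuration
#'
#' Parameters of the synthetic session generator. The defaults emulate the
#' statistical structure the analyses assume, at desk scale: log-normally
#' distributed baseline rates with FS units firing faster than RS units, a
#' bimodal spike-width mixture well clear of the 0.26/0.34-ms
#' classification gap, area- and class-specific whisker-evoked transients
#' whose window-averaged amplitudes follow the published group means
#' (including evoked suppression in tjM1 and delay-period activity in ALM),
#' and an optional list of short-lag "synaptic" couplings injected between
#' unit pairs.
#'
#' @param n_units named numeric, units per cell class (`RS`, `FS`) in every
#'   area.
#' @param areas cortical areas to simulate.
#' @param group `"Novice"` or `"Expert"`; selects the evoked-template
#'   amplitude set.
#' @param trial_counts named counts per outcome (`hit`, `miss`, `CR`, `FA`).
#' @param rate_params per-class log-normal baseline-rate parameters
#'   (`mu_log`, `sigma_log` of the log-rate).
#' @param width_params per-class spike-width mean/SD in ms.
#' @param templates data.frame of evoked templates (see
#'   [default_evoked_templates()]); `NULL` uses the defaults for `group`.
#' @param connections data.frame with columns `pre_unit`, `post_unit`,
#'   `efficacy` (in \[0,1\]), `delay_ms`, `jitter_ms`, or `NULL`.
#' @param opto list of opto-stimulation parameters (see
#'   [default_opto_params()]).
#' @param trial_spacing_s inter-trial onset spacing in seconds.
#' @param seed master seed; per-unit substreams are derived from it by a
#'   counter so adding units does not perturb existing ones.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_units = c(RS = 12, FS = 6),
                       areas = .DEFAULT_AREAS,
                       group = c("Expert", "Novice"),
                       trial_counts = c(hit = 40, miss = 10, CR = 40, FA = 10),
                       rate_params = list(
                         RS = c(mu_log = log(2.0), sigma_log = 0.9),
                         FS = c(mu_log = log(6.0), sigma_log = 0.7)),
                       width_params = list(
                         RS = c(mean = 0.55, sd = 0.06),
                         FS = c(mean = 0.19, sd = 0.02)),
                       templates = NULL,
                       connections = NULL,
                       opto = default_opto_params(),
                       trial_spacing_s = 10,
                       seed = 1) {
  group <- match.arg(group)
  if (any(n_units < 0) || any(trial_counts < 0))
    stop("config error: counts must be non-negative")
  if (!is.null(connections)) {
    if (any(connections$efficacy < 0 | connections$efficacy > 1))
      stop("config error: efficacy must lie in [0, 1]")
    if (any(connections$delay_ms <= 0))
      stop("config error: connection delay must be > 0")
  }
  if (width_params$FS["mean"] >= 0.26 || width_params$RS["mean"] <= 0.34)
    warning("width means overlap the RS/FS exclusion zone")
  if (is.null(templates)) templates <- default_evoked_templates(group)
  structure(list(n_units = n_units, areas = areas, group = group,
                 trial_counts = trial_counts, rate_params = rate_params,
                 width_params = width_params, templates = templates,
                 connections = connections, opto = opto,
                 trial_spacing_s = trial_spacing_s, seed = seed),
            class = "sim_config")
}

#' Default evoked-response templates
#'
#' One template per area and cell class. `amplitude_hz` is the
#' window-averaged change in firing rate the template produces inside its
#' reference window (so generated cohorts reproduce the published group
#' means), `latency_ms` shifts the kernel onset, and `rise_ms`/`decay_ms`
#' are the time constants of the difference-of-exponentials kernel. The
#' sensory and motor areas use fast transients; ALM uses a slow kernel
#' filling the delay period; tjM1 amplitudes are negative (evoked
#' suppression) in Expert mice.
#'
#' @param group `"Novice"` or `"Expert"`.
#' @return data.frame of templates.
#' @export
default_evoked_templates <- function(group = c("Expert", "Novice")) {
  group <- match.arg(group)
  amp <- if (group == "Novice") {
    c(wS1_RS = 6.0, wS1_FS = 13.9, wS2_RS = 4.0, wS2_FS = 12.2,
      wM1_RS = 1.8, wM1_FS = 3.1, wM2_RS = 1.0, wM2_FS = 4.5,
      ALM_RS = 0.1, ALM_FS = 0.2, tjM1_RS = 0.0, tjM1_FS = -0.2)
  } else {
    c(wS1_RS = 5.3, wS1_FS = 11.9, wS2_RS = 4.3, wS2_FS = 11.5,
      wM1_RS = 0.9, wM1_FS = 7.3, wM2_RS = 1.5, wM2_FS = 2.7,
      ALM_RS = 1.4, ALM_FS = 3.7, tjM1_RS = -0.6, tjM1_FS = -1.5)
  }
  lat <- c(wS1 = 8, wS2 = 11, wM1 = 20, wM2 = 25, ALM = 150, tjM1 = 35)
  rise <- c(wS1 = 3, wS2 = 3, wM1 = 5, wM2 = 5, ALM = 100, tjM1 = 8)
  decay <- c(wS1 = 15, wS2 = 15, wM1 = 25, wM2 = 25, ALM = 500, tjM1 = 30)
  wmap <- area_window_map()
  cfg <- default_window_config()
  rows <- lapply(names(amp), function(key) {
    parts <- strsplit(key, "_")[[1]]
    a <- parts[1]; cc <- parts[2]
    w <- window_lookup(cfg, wmap[[a]])$window
    data.frame(area = a, cell_class = cc, amplitude_hz = unname(amp[key]),
               latency_ms = unname(lat[a]), rise_ms = unname(rise[a]),
               decay_ms = unname(decay[a]),
               win_start_s = w[1], win_end_s = w[2])
  })
  do.call(rbind, rows)
}

#' Default opto-stimulation parameters
#'
#' Emulates 600-ms trains of 100-Hz blue light pulses: tagged (ground-truth
#' GABAergic) units respond with a short-latency, low-jitter first spike and
#' an elevated rate during the train; untagged units are suppressed by a
#' multiplicative factor.
#' @return named list.
#' @export
default_opto_params <- function() {
  list(n_trains = 50, train_duration_s = 0.6, spacing_s = 5,
       latency_ms = 2, jitter_ms = 0.3, fidelity = 0.9,
       light_factor = 8, suppression = 0.3)
}

.unit_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 10007 * counter) %% 2147483647)
}

# difference-of-exponentials kernel, onset-shifted; t in seconds
.template_kernel <- function(t_rel, latency_s, rise_s, decay_s) {
  u <- t_rel - latency_s
  k <- ifelse(u > 0, exp(-u / decay_s) - exp(-u / rise_s), 0)
  k
}

# scale factor making the kernel's mean over [w1, w2] equal 1
.template_scale <- function(latency_s, rise_s, decay_s, w1, w2) {
  tt <- seq(w1, w2, by = 1e-4)
  m <- mean(.template_kernel(tt, latency_s, rise_s, decay_s))
  if (m <= 0) stop("config error: template kernel has no mass in its window")
  1 / m
}

# homogeneous Poisson spikes on [t0, t1)
.gen_pois <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

.make_strict <- function(x) unique(round(sort(x), 6))

#' Generate a synthetic behavioural session with known ground truth
#'
#' Units are inhomogeneous Poisson processes with rate
#' `r(t) = max(0, baseline + sum of active evoked templates)`; whisker
#' templates are only active on whisker-stimulus trials. Spiking is exact:
#' baseline segments are drawn directly and template-affected segments by
#' thinning against the local rate bound. Optional short-lag couplings then
#' spawn extra post-synaptic spikes from the pre-synaptic train
#' ([inject_connection()]). Reproducible given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements `session` (a `spike_session`) and `truth`
#'   (ground-truth unit table, template table, connection list).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  trials <- .make_trial_table(config)
  whisker <- trials$whisker_onset_s[!is.na(trials$whisker_onset_s)]
  span <- c(0, max(trials$auditory_onset_s) + 3)

  units <- list(); spikes <- list(); waveforms <- list()
  counter <- 0L
  for (area in config$areas) for (cc in names(config$n_units)) {
    n <- config$n_units[[cc]]
    if (n <= 0) next
    tmpl <- config$templates[config$templates$area == area &
                             config$templates$cell_class == cc, ,
                             drop = FALSE]
    for (j in seq_len(n)) {
      counter <- counter + 1L
      us <- .unit_seed(config$seed, counter)
      set.seed(us)
      id <- sprintf("%s_%s_%02d", area, cc, j)
      rp <- config$rate_params[[cc]]
      b <- stats::rlnorm(1, rp[["mu_log"]], rp[["sigma_log"]])
      wp <- config$width_params[[cc]]
      width <- max(0.08, stats::rnorm(1, wp[["mean"]], wp[["sd"]]))
      st <- .gen_unit_spikes(b, tmpl, whisker, span)
      wf <- .unit_waveforms(width, seed = us + 1L)
      units[[id]] <- data.frame(
        unit_id = id, area = area, layer = sample(c("L2/3", "L5", "L6a"), 1),
        assigned_site = 2L, spike_width_ms = NA_real_,
        cell_class = cc, baseline_rate_hz = NA_real_,
        true_width_ms = width, true_baseline_hz = b,
        true_amplitude_hz = if (nrow(tmpl)) tmpl$amplitude_hz[1] else 0,
        true_latency_ms = if (nrow(tmpl)) tmpl$latency_ms[1] else NA_real_)
      spikes[[id]] <- st
      waveforms[[id]] <- wf
    }
  }
  truth_units <- do.call(rbind, units)
  rownames(truth_units) <- NULL

  if (!is.null(config$connections)) {
    for (i in seq_len(nrow(config$connections))) {
      cn <- config$connections[i, ]
      extra <- inject_connection(spikes[[cn$pre_unit]], cn$efficacy,
                                 cn$delay_ms, cn$jitter_ms,
                                 seed = .unit_seed(config$seed, 100000L + i))
      spikes[[cn$post_unit]] <-
        .make_strict(c(spikes[[cn$post_unit]], extra))
    }
  }

  utab <- truth_units[, c("unit_id", "area", "layer", "assigned_site",
                          "spike_width_ms", "cell_class",
                          "baseline_rate_hz")]
  # stored class must stay consistent with (yet unmeasured) width
  utab$spike_width_ms <- NA_real_
  s <- session(utab, spikes, trials, waveforms = waveforms,
               session_id = sprintf("sim_%s_%d", config$group, config$seed),
               group = config$group)
  truth <- list(units = truth_units, templates = config$templates,
                connections = config$connections)
  list(session = s, truth = truth)
}

.make_trial_table <- function(config) {
  tc <- config$trial_counts
  outs <- rep(names(tc), tc)
  outs <- sample(outs)
  n <- length(outs)
  visual <- 5 + (seq_len(n) - 1) * config$trial_spacing_s
  whisk <- ifelse(outs %in% c("hit", "miss"), visual + 1, NA_real_)
  aud <- visual + 2
  lick <- ifelse(outs %in% c("hit", "FA"),
                 aud + stats::runif(n, 0.1, 0.5), NA_real_)
  data.frame(trial_id = seq_len(n), visual_onset_s = visual,
             whisker_onset_s = whisk, auditory_onset_s = aud,
             outcome = outs, first_lick_s = round(lick, 6),
             light_on = FALSE)
}

# exact inhomogeneous-Poisson sampling: direct draws on baseline-only
# segments, thinning on template-affected segments around each whisker onset
.gen_unit_spikes <- function(baseline, tmpl, whisker_onsets, span) {
  if (nrow(tmpl) == 0 || length(whisker_onsets) == 0 ||
      all(tmpl$amplitude_hz == 0)) {
    return(.make_strict(.gen_pois(baseline, span[1], span[2])))
  }
  lat <- tmpl$latency_ms / 1000
  rise <- tmpl$rise_ms / 1000
  decay <- tmpl$decay_ms / 1000
  scale <- mapply(.template_scale, lat, rise, decay,
                  tmpl$win_start_s, tmpl$win_end_s)
  sup_end <- max(lat + 8 * decay, tmpl$win_end_s)
  delta <- function(t_rel) {
    out <- 0
    for (k in seq_len(nrow(tmpl)))
      out <- out + tmpl$amplitude_hz[k] * scale[k] *
        .template_kernel(t_rel, lat[k], rise[k], decay[k])
    out
  }
  peak <- max(0, max(delta(seq(0, sup_end, by = 1e-4))))
  rmax <- baseline + peak
  spikes <- numeric(0)
  bounds <- sort(c(span[1], as.vector(rbind(whisker_onsets,
                                            whisker_onsets + sup_end)),
                   span[2]))
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    active <- any(whisker_onsets <= t0 & t0 < whisker_onsets + sup_end)
    if (!active) {
      spikes <- c(spikes, .gen_pois(baseline, t0, t1))
    } else {
      w0 <- max(whisker_onsets[whisker_onsets <= t0])
      cand <- .gen_pois(rmax, t0, t1)
      if (length(cand)) {
        r <- pmax(0, baseline + delta(cand - w0))
        keep <- stats::runif(length(cand)) < r / rmax
        spikes <- c(spikes, cand[keep])
      }
    }
  }
  .make_strict(spikes)
}

.unit_waveforms <- function(width_ms, seed, n_sites = 3L) {
  amps <- c(55, 100, 40)
  lapply(seq_len(n_sites), function(k)
    synth_waveform(width_ms, amplitude = amps[k], noise_sd = 0,
                   sampling_rate = 30000, seed = seed + k, site_index = k))
}

#' Synthesise a biphasic spike waveform of known width
#'
#' Constructs a baseline-referenced waveform whose trough-to-baseline-return
#' duration equals `width_ms` (to within one sample at `noise_sd = 0`): a
#' flat baseline, a half-cosine descent to the trough, a linear rise crossing
#' baseline exactly `width_ms` after the trough, and a small positive
#' after-lobe.
#'
#' @param width_ms target spike width in ms.
#' @param amplitude trough depth (arbitrary units, must be > 0).
#' @param noise_sd SD of additive Gaussian noise.
#' @param sampling_rate sampling rate, Hz.
#' @param seed seed for the noise draw.
#' @param site_index stored site index.
#' @return a [waveform()].
#' @export
synth_waveform <- function(width_ms, amplitude = 100, noise_sd = 0,
                           sampling_rate = 30000, seed = 1, site_index = 1L) {
  if (width_ms <= 0) stop("width_ms must be > 0")
  if (amplitude <= 0) stop("width undefined: amplitude must be > 0")
  ws <- width_ms / 1000 * sampling_rate
  if (ws < 2) stop("width shorter than 2 samples at this sampling rate")
  d <- 6L
  tail_n <- 16L
  rise_n <- as.integer(ceiling(ws))
  n_base <- max(24L, as.integer(ceiling((d + rise_n + tail_n) / 3)) + 2L)
  descent <- -amplitude * sin(pi / 2 * seq_len(d) / d)
  risej <- seq_len(rise_n)
  rise <- -amplitude * (1 - risej / ws)
  v_end <- rise[rise_n]
  lobe_n <- 10L
  lobe <- v_end + (0.15 * amplitude - v_end) *
    sin(pi * seq_len(lobe_n) / lobe_n)^2
  v <- c(rep(0, n_base), descent, rise, lobe, rep(0, tail_n - lobe_n))
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  waveform(v, sampling_rate, site_index)
}

#' Inject a monosynaptic-like coupling between two spike trains
#'
#' Each pre-synaptic spike independently spawns one post-synaptic spike at
#' `t + delay + Normal(0, jitter)` with probability `efficacy`.
#'
#' @param pre_spike_times pre-synaptic spike times (s).
#' @param efficacy spawn probability in \[0, 1\].
#' @param delay_ms synaptic delay, ms (> 0).
#' @param jitter_ms SD of the Gaussian timing jitter, ms.
#' @param seed seed.
#' @return sorted vector of spawned post-synaptic spike times.
#' @export
inject_connection <- function(pre_spike_times, efficacy, delay_ms,
                              jitter_ms = 0, seed = 1) {
  if (efficacy < 0 || efficacy > 1) stop("efficacy must lie in [0, 1]")
  if (delay_ms <= 0) stop("delay_ms must be > 0")
  set.seed(seed)
  keep <- stats::runif(length(pre_spike_times)) < efficacy
  t <- pre_spike_times[keep] + delay_ms / 1000
  if (jitter_ms > 0) t <- t + stats::rnorm(length(t), 0, jitter_ms / 1000)
  sort(t)
}

#' Generate a synthetic opto-tagging session
#'
#' Emulates recordings during 600-ms trains of 100-Hz blue light pulses.
#' Ground-truth GABAergic (FS) units are "tagged": on each train, with
#' probability `fidelity`, they emit a first spike at the configured
#' latency/jitter after train onset, and their rate is multiplied by
#' `light_factor` for the train duration. Untagged (RS) units have their
#' rate multiplied by `suppression` during the light.
#'
#' @param config a [sim_config()]; its `opto` element must be present.
#' @return list with `session` (containing `light_pulses`) and `truth`
#'   (including the logical `tagged` column).
#' @export
generate_opto_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  op <- config$opto
  if (is.null(op)) stop("config error: opto parameters missing")
  if (op$fidelity < 0 || op$fidelity > 1)
    stop("config error: fidelity must lie in [0, 1]")
  set.seed(config$seed)
  onsets <- 10 + (seq_len(op$n_trains) - 1) * op$spacing_s
  span <- c(0, max(onsets) + 3)
  units <- list(); spikes <- list(); waveforms <- list()
  counter <- 0L
  for (cc in names(config$n_units)) {
    n <- config$n_units[[cc]]
    for (j in seq_len(n)) {
      counter <- counter + 1L
      us <- .unit_seed(config$seed, 200000L + counter)
      set.seed(us)
      id <- sprintf("wS1_%s_%02d", cc, j)
      rp <- config$rate_params[[cc]]
      b <- stats::rlnorm(1, rp[["mu_log"]], rp[["sigma_log"]])
      wp <- config$width_params[[cc]]
      width <- max(0.08, stats::rnorm(1, wp[["mean"]], wp[["sd"]]))
      tagged <- cc == "FS"
      st <- .gen_opto_spikes(b, tagged, onsets, op, span)
      units[[id]] <- data.frame(
        unit_id = id, area = "wS1", layer = "L5", assigned_site = 2L,
        spike_width_ms = NA_real_, cell_class = cc,
        baseline_rate_hz = NA_real_, true_width_ms = width,
        true_baseline_hz = b, tagged = tagged)
      spikes[[id]] <- st
      waveforms[[id]] <- .unit_waveforms(width, seed = us + 1L)
    }
  }
  truth_units <- do.call(rbind, units)
  rownames(truth_units) <- NULL
  utab <- truth_units[, c("unit_id", "area", "layer", "assigned_site",
                          "spike_width_ms", "cell_class",
                          "baseline_rate_hz")]
  trials <- data.frame(trial_id = integer(), visual_onset_s = numeric(),
                       whisker_onset_s = numeric(),
                       auditory_onset_s = numeric(), outcome = character(),
                       first_lick_s = numeric(), light_on = logical())
  s <- session(utab, spikes, trials, waveforms = waveforms,
               light_pulses = onsets,
               session_id = sprintf("sim_opto_%d", config$seed),
               group = config$group)
  list(session = s,
       truth = list(units = truth_units, opto = op))
}

.gen_opto_spikes <- function(baseline, tagged, onsets, op, span) {
  dur <- op$train_duration_s
  light_rate <- if (tagged) baseline * op$light_factor
                else baseline * op$suppression
  spikes <- .gen_pois(baseline, span[1], onsets[1])
  for (i in seq_along(onsets)) {
    t0 <- onsets[i]
    spikes <- c(spikes, .gen_pois(light_rate, t0, t0 + dur))
    t_next <- if (i < length(onsets)) onsets[i + 1] else span[2]
    spikes <- c(spikes, .gen_pois(baseline, t0 + dur, t_next))
    if (tagged && stats::runif(1) < op$fidelity) {
      first <- t0 + op$latency_ms / 1000 +
        stats::rnorm(1, 0, op$jitter_ms / 1000)
      # drop any earlier background spike in the tag window so the
      # configured first-spike latency is the one observed
      in_win <- spikes >= t0 & spikes < first
      spikes <- c(spikes[!in_win], max(t0, first))
    }
  }
  .make_strict(spikes)
}
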