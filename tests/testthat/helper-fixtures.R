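# Shared fixture builders. All synthetic; built in code at test time.

# Regular trial table: visual at t, whisker at t+1 (stim trials),
# auditory at t+2, trials spaced 10 s.
make_trials <- function(n = 20, outcomes = rep("hit", n), spacing = 10) {
  n <- length(outcomes)
  visual <- 5 + (seq_len(n) - 1) * spacing
  whisk <- ifelse(outcomes %in% c("hit", "miss"), visual + 1, NA_real_)
  data.frame(trial_id = seq_len(n), visual_onset_s = visual,
             whisker_onset_s = whisk, auditory_onset_s = visual + 2,
             outcome = outcomes,
             first_lick_s = ifelse(outcomes %in% c("hit", "FA"),
                                   visual + 2.3, NA_real_),
             light_on = FALSE)
}

# Homogeneous Poisson train over [0, t_end)
poisson_train <- function(rate, t_end, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, rate * t_end)
  sort(runif(n, 0, t_end))
}

# Minimal valid session with given per-unit spike trains
make_session <- function(spikes, trials, areas = "wS1",
                         classes = "RS", ...) {
  ids <- names(spikes)
  units <- data.frame(unit_id = ids,
                      area = rep_len(areas, length(ids)),
                      layer = "L5", assigned_site = 1L,
                      spike_width_ms = NA_real_,
                      cell_class = rep_len(classes, length(ids)))
  session(units, spikes, trials, ...)
}

# binned_trial_spikes built directly from a sparse (trial, bin) table
make_binned <- function(spk, n_bins, n_trials, bin_width_s = 0.001) {
  structure(list(spk = spk, n_trials = n_trials, n_bins = n_bins,
                 bin_width_s = bin_width_s,
                 lambda = nrow(spk) / (n_trials * n_bins),
                 rate_hz = nrow(spk) / (n_trials * n_bins) / bin_width_s),
            class = "binned_trial_spikes")
}
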