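test_that("PSTH places unit spike mass in the event bin", {
  tr <- make_trials(1)
  st <- tr$whisker_onset_s[1] + 0.0005  # inside the first post-event bin
  ps <- compute_psth(st, tr, span = c(-0.1, 0.1), sigma_s = 0)
  expect_equal(sum(ps$rate_hz > 0), 1)
  expect_equal(max(ps$rate_hz), 1000)  # 1 spike / (1 trial * 1 ms)
  expect_equal(ps$bin_centers_s[which.max(ps$rate_hz)], 0.0005)
})

test_that("PSTH recovers a homogeneous Poisson rate", {
  tr <- make_trials(500, spacing = 4)
  st <- poisson_train(10, max(tr$auditory_onset_s) + 1, seed = 23)
  ps <- compute_psth(st, tr, span = c(-0.3, 0.3), sigma_s = 0.01)
  expect_true(all(abs(ps$rate_hz - 10) < 1.5 + 3 * sqrt(10 / (500 * 0.02))))
  expect_lt(abs(mean(ps$rate_hz) - 10), 0.5)
})

test_that("Gaussian smoothing conserves interior spike mass", {
  tr <- make_trials(20)
  st <- poisson_train(15, max(tr$auditory_onset_s), seed = 29)
  raw <- compute_psth(st, tr, span = c(-0.25, 0.25), sigma_s = 0)
  sm <- compute_psth(st, tr, span = c(-0.25, 0.25), sigma_s = 0.01)
  tot_raw <- sum(raw$rate_hz) * raw$bin_width_s
  tot_sm <- sum(sm$rate_hz) * sm$bin_width_s
  expect_lt(abs(tot_raw - tot_sm) / tot_raw, 0.02)  # reflection edge only
  # interior mass: identical up to numerical noise when spikes are
  # far from the window edges
  tr1 <- make_trials(1)
  st1 <- tr1$whisker_onset_s[1] + 0.0005
  raw1 <- compute_psth(st1, tr1, span = c(-0.2, 0.2), sigma_s = 0)
  sm1 <- compute_psth(st1, tr1, span = c(-0.2, 0.2), sigma_s = 0.01)
  expect_lt(abs(sum(raw1$rate_hz) - sum(sm1$rate_hz)) / sum(raw1$rate_hz),
            1e-6)
  expect_error(compute_psth(st, tr, outcomes = "FA"), "no trials")
})

test_that("evoked response delta is the window rate difference", {
  tr <- make_trials(10)
  # 5 spikes in each 100-ms response window, 2 in each 100-ms baseline
  resp <- as.vector(outer(seq(0.005, 0.095, length.out = 5),
                          tr$whisker_onset_s, "+"))
  base <- as.vector(outer(c(-0.07, -0.02), tr$whisker_onset_s, "+"))
  st <- sort(c(resp, base))
  er <- evoked_response(st, tr, c(0, 0.1), c(-0.1, 0), n_perm = 500)
  expect_equal(er$delta_rate_hz, 30)
  expect_equal(er$direction, "positive")
  # invariant to spikes strictly outside both windows
  st2 <- sort(c(st, tr$visual_onset_s - 3, tr$auditory_onset_s + 0.5))
  er2 <- evoked_response(st2, tr, c(0, 0.1), c(-0.1, 0), n_perm = 500)
  expect_equal(er2$delta_rate_hz, er$delta_rate_hz)
  expect_equal(er2$p_value, er$p_value)
  # no spikes at all
  er0 <- evoked_response(numeric(0), tr, c(0, 0.1), c(-0.1, 0))
  expect_equal(er0$delta_rate_hz, 0)
  expect_equal(er0$direction, "none")
})

test_that("generator template amplitude is recovered by evoked_response", {
  tmpl <- data.frame(area = "wM1", cell_class = "RS", amplitude_hz = 8,
                     latency_ms = 15, rise_ms = 5, decay_ms = 25,
                     win_start_s = 0.01, win_end_s = 0.09)
  g <- generate_session(sim_config(n_units = c(RS = 40, FS = 0),
                                   areas = "wM1", templates = tmpl,
                                   trial_counts = c(hit = 40, miss = 0,
                                                    CR = 0, FA = 0),
                                   seed = 61))
  er <- session_evoked_responses(g$session, n_perm = 200, seed = 2)
  # mean over 40 units of a +8 Hz in-window template
  se <- sd(er$delta_rate_hz) / sqrt(nrow(er))
  expect_lt(abs(mean(er$delta_rate_hz) - 8), 3 * se + 0.5)
})

test_that("modulated fractions count one-sided calls and flag small groups", {
  resp <- data.frame(area = rep(c("wS1", "wM1"), c(8, 4)),
                     cell_class = "RS",
                     p_positive = c(rep(0.001, 8), rep(0.5, 4)),
                     p_negative = c(rep(0.9, 8), rep(0.5, 4)))
  fr <- modulated_fractions(resp, threshold = 0.025)
  ws1 <- fr[fr$area == "wS1", ]
  expect_equal(ws1$frac_positive, 1.0)
  expect_equal(ws1$frac_negative, 0.0)
  expect_true(ws1$reportable)
  expect_false(fr$reportable[fr$area == "wM1"])  # n = 4 <= 5
})

test_that("null fractions match the nominal test level", {
  # 200 null units, exhaustive paired test on 12 trials: the fraction
  # of one-sided calls at 0.025 should be near 0.025 each way
  set.seed(67)
  n_units <- 200
  pp <- pn <- numeric(n_units)
  for (i in seq_len(n_units)) {
    d <- rnorm(12)
    pp[i] <- permutation_test_paired(d, alternative = "greater")$p_value
    pn[i] <- permutation_test_paired(d, alternative = "less")$p_value
  }
  ci <- 2.576 * sqrt(0.025 * 0.975 / n_units)
  expect_lt(abs(mean(pp < 0.025) - 0.025), ci + 0.01)
  expect_lt(abs(mean(pn < 0.025) - 0.025), ci + 0.01)
})

test_that("group comparison detects a learning effect and is symmetric", {
  set.seed(71)
  novice <- rnorm(150, mean = 1.8, sd = 2)
  expert <- rnorm(450, mean = 0.9, sd = 2)
  r <- compare_groups(novice, expert, n_perm = 2000, seed = 1)
  expect_lt(r$p_value, 0.01)
  r2 <- compare_groups(expert, novice, n_perm = 2000, seed = 1)
  expect_equal(r$statistic, -r2$statistic)
  # identical populations: p well away from 0
  same <- rnorm(100)
  expect_gt(compare_groups(same, same, n_perm = 1000, seed = 2)$p_value,
            0.99)
})

test_that("outcome contrast detects an outcome-specific rate change", {
  # CR trials carry 2 Hz less activity in the response window
  set.seed(73)
  detected <- 0
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    outs <- rep(c("miss", "CR"), each = 15)
    tr <- make_trials(30, outcomes = sample(outs))
    st <- numeric(0)
    for (k in seq_len(nrow(tr))) {
      rate <- if (tr$outcome[k] == "CR") 3 else 5
      st <- c(st, tr$auditory_onset_s[k] +
                sort(runif(rpois(1, rate), 0, 1)))
    }
    st <- sort(st)
    r <- outcome_contrast(st, tr, "CR", "miss", window = c(0, 1),
                          n_perm = 500, seed = i)
    if (r$p_value < 0.05 && r$statistic < 0) detected <- detected + 1
  }
  expect_gte(detected / n_rep, 0.5)  # 2-Hz effect over 15+15 trials
  # single trial per subset: runs with a warning
  tr1 <- make_trials(2, outcomes = c("CR", "miss"))
  expect_warning(outcome_contrast(c(tr1$auditory_onset_s + 0.1), tr1,
                                  "CR", "miss", c(0, 1)),
                 "single trial")
})
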