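test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_units = c(RS = 2, FS = 2), areas = c("wS1", "ALM"),
                    trial_counts = c(hit = 8, miss = 2, CR = 8, FA = 2),
                    seed = 9)
  g1 <- generate_session(cfg)
  g2 <- generate_session(cfg)
  expect_identical(g1$session$spikes, g2$session$spikes)
  expect_identical(g1$session$trials, g2$session$trials)
  expect_identical(g1$truth$units, g2$truth$units)
  # per-unit substreams: adding units must not perturb existing ones
  cfg_big <- sim_config(n_units = c(RS = 3, FS = 2),
                        areas = c("wS1", "ALM"),
                        trial_counts = c(hit = 8, miss = 2, CR = 8, FA = 2),
                        seed = 9)
  g3 <- generate_session(cfg_big)
  expect_identical(g1$session$spikes[["wS1_RS_01"]],
                   g3$session$spikes[["wS1_RS_01"]])
})

test_that("log-normal baseline parameters are recovered from a large cohort", {
  set.seed(101)
  rates <- rlnorm(2000, meanlog = 1.0, sdlog = 0.5)
  fit <- fit_lognormal_rates(rates)
  expect_lt(abs(fit$mu_log - 1.0), 0.05)
  expect_lt(abs(fit$sigma_log - 0.5), 0.05)
})

test_that("zero evoked amplitude yields deltas centred on zero", {
  tmpl <- default_evoked_templates("Expert")
  tmpl$amplitude_hz <- 0
  g <- generate_session(sim_config(n_units = c(RS = 6, FS = 0),
                                   areas = "wS1", templates = tmpl,
                                   trial_counts = c(hit = 30, miss = 0,
                                                    CR = 0, FA = 0),
                                   seed = 21))
  er <- session_evoked_responses(g$session, n_perm = 200, seed = 1)
  # mean delta across units should be near 0 (no template); bound by
  # 3 * SE of a Poisson rate difference over trials and units
  expect_lt(abs(mean(er$delta_rate_hz)), 3)
})

test_that("synth_waveform width survives the measurement round trip", {
  for (w in c(0.20, 0.333, 0.50, 0.70)) {
    wf <- synth_waveform(w, sampling_rate = 30000, seed = 1)
    expect_lt(abs(compute_spike_width(wf) - w), 1 / 30, label = paste(w))
  }
  expect_equal(classify_rs_fs(compute_spike_width(
    synth_waveform(0.20, sampling_rate = 30000))), "FS")
  expect_error(synth_waveform(0.5, amplitude = 0), "width undefined")
  expect_error(synth_waveform(0.00005), "2 samples")
})

test_that("inject_connection spawns spikes per the binomial contract", {
  pre <- 0.5 + (0:9999) * 0.01
  # efficacy 1, no jitter: exact 3-ms shift
  post <- inject_connection(pre, efficacy = 1, delay_ms = 3, jitter_ms = 0,
                            seed = 2)
  expect_equal(post, pre + 0.003)
  expect_length(inject_connection(pre, efficacy = 0, delay_ms = 3), 0)
  # efficacy 0.1: binomial count within 3 SD
  n <- length(inject_connection(pre, efficacy = 0.1, delay_ms = 3,
                                jitter_ms = 0.2, seed = 3))
  expect_lt(abs(n - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_error(inject_connection(pre, efficacy = 1.5, delay_ms = 3),
               "efficacy")
})

test_that("generated spike counts are Poisson with the configured rate", {
  # baseline-only unit: counts in 100 disjoint windows vs Poisson law
  g <- generate_session(sim_config(n_units = c(RS = 1, FS = 0),
                                   areas = "wS1",
                                   rate_params = list(
                                     RS = c(mu_log = log(8), sigma_log = 0),
                                     FS = c(mu_log = log(8), sigma_log = 0)),
                                   templates = within(
                                     default_evoked_templates("Expert"),
                                     amplitude_hz <- 0),
                                   trial_counts = c(hit = 50, miss = 0,
                                                    CR = 50, FA = 0),
                                   seed = 31))
  st <- g$session$spikes[[1]]
  b <- g$truth$units$true_baseline_hz[1]
  windows <- seq(0, 990, by = 10)[1:100]
  counts <- vapply(windows, function(t0)
    sum(st >= t0 & st < t0 + 5), 0)
  lam <- b * 5
  # chi-square GOF on binned counts
  brks <- c(-Inf, qpois(c(0.2, 0.4, 0.6, 0.8), lam), Inf)
  obs <- table(cut(counts, brks))
  pr <- diff(c(0, ppois(qpois(c(0.2, 0.4, 0.6, 0.8), lam), lam), 1))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("rates are rectified at zero under suppression templates", {
  tmpl <- data.frame(area = "tjM1", cell_class = "RS",
                     amplitude_hz = -50, latency_ms = 10, rise_ms = 5,
                     decay_ms = 20, win_start_s = 0.04, win_end_s = 0.09)
  g <- generate_session(sim_config(n_units = c(RS = 3, FS = 0),
                                   areas = "tjM1", templates = tmpl,
                                   trial_counts = c(hit = 20, miss = 0,
                                                    CR = 0, FA = 0),
                                   seed = 41))
  # a strongly negative template cannot produce negative rates: spike
  # trains remain valid (strictly increasing, finite)
  for (st in g$session$spikes) {
    expect_true(all(is.finite(st)))
    if (length(st) > 1) expect_true(all(diff(st) > 0))
  }
})

test_that("opto session reproduces configured tag metrics and OMI", {
  op <- modifyList(default_opto_params(),
                   list(fidelity = 1.0, latency_ms = 2, jitter_ms = 0.3))
  og <- generate_opto_session(sim_config(n_units = c(RS = 0, FS = 1),
                                         opto = op, seed = 51))
  st <- og$session$spikes[[1]]
  m <- fast_response_metrics(st, og$session$light_pulses)
  expect_equal(m$fidelity_pct, 100)
  expect_lt(abs(m$latency_ms - 2), 0.5)
  expect_lt(abs(m$jitter_ms - 0.3), 0.2)

  # suppression factor 0.4 on a 5-Hz unit: OMI near (2-5)/(2+5)
  op2 <- modifyList(default_opto_params(),
                    list(suppression = 0.4, n_trains = 200))
  og2 <- generate_opto_session(sim_config(
    n_units = c(RS = 1, FS = 0),
    rate_params = list(RS = c(mu_log = log(5), sigma_log = 0),
                       FS = c(mu_log = log(5), sigma_log = 0)),
    opto = op2, seed = 52))
  r <- opto_rates(og2$session$spikes[[1]], og2$session$light_pulses)
  expect_lt(abs(opto_modulation_index(r) - (2 - 5) / (2 + 5)), 0.12)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_units = c(RS = -1, FS = 2)), "config error")
  expect_error(sim_config(connections = data.frame(
    pre_unit = "a", post_unit = "b", efficacy = 2, delay_ms = 3,
    jitter_ms = 0)), "efficacy")
  og <- sim_config(n_units = c(RS = 1, FS = 1), seed = 1)
  og$opto <- NULL
  expect_error(generate_opto_session(og), "opto parameters missing")
})
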