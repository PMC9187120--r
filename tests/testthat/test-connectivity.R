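test_that("STTC matches the hand-computed example and its identities", {
  s <- sttc(c(0.100, 0.500), c(0.105), interval = c(0, 1))
  expect_equal(s$P_A, 0.5)
  expect_equal(s$P_B, 1)
  expect_equal(s$T_A, 0.04)
  expect_equal(s$T_B, 0.02)
  expect_equal(round(s$value, 4), 0.7424)
  # identical trains give 1
  tr <- sort(runif(20))
  expect_equal(sttc(tr, tr, c(0, 1))$value, 1)
  # symmetry in (A, B)
  set.seed(7)
  a <- sort(runif(30)); b <- sort(runif(25))
  expect_equal(sttc(a, b, c(0, 1))$value, sttc(b, a, c(0, 1))$value)
  # bounds
  for (i in 1:20) {
    x <- sort(runif(sample(2:40, 1)))
    y <- sort(runif(sample(2:40, 1)))
    v <- sttc(x, y, c(0, 1))$value
    expect_gte(v, -1); expect_lte(v, 1)
  }
  # empty train: undefined, flagged
  expect_warning(v <- sttc(numeric(0), a, c(0, 1))$value, "undefined")
  expect_true(is.na(v))
})

test_that("STTC is centred on zero for independent Poisson pairs", {
  set.seed(11)
  vals <- vapply(1:300, function(i) {
    suppressWarnings(  # rare empty trains are NA and dropped below
      sttc(poisson_train(5, 1), poisson_train(5, 1), c(0, 1))$value)
  }, 0)
  vals <- vals[!is.na(vals)]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("raw CCG matches the single-pair hand computation", {
  # M=1 trial, N=10 bins, ref spike in bin 3, target in bin 5
  a <- make_binned(data.frame(trial = 1L, bin = 3L), 10L, 1L)
  b <- make_binned(data.frame(trial = 1L, bin = 5L), 10L, 1L)
  r <- suppressWarnings(ccg(a, b, max_lag_s = 0.005))
  at <- function(lag_s) r$ccg_raw[abs(r$lags_s - lag_s) < 1e-9]
  expect_equal(at(0.002), 1 / (8 * 0.1 * 0.1))  # 12.5
  expect_equal(at(0), 0)
  expect_equal(at(-0.002), 0)
})

test_that("CCG is normalized to 1 for independent stationary pairs", {
  tr <- make_trials(200, spacing = 4)
  t_end <- max(tr$auditory_onset_s) + 1
  b1 <- bin_trial_spikes(poisson_train(10, t_end, seed = 13), tr)
  b2 <- bin_trial_spikes(poisson_train(10, t_end, seed = 14), tr)
  r <- ccg(b1, b2)
  mc_se <- sd(r$ccg_raw) / sqrt(length(r$ccg_raw))
  expect_lt(abs(mean(r$ccg_raw) - 1), 3 * mc_se + 0.01)
})

test_that("a shifted-copy target produces a CCG peak at the shift", {
  tr <- make_trials(50, spacing = 4)
  t_end <- max(tr$auditory_onset_s) + 1
  pre <- poisson_train(8, t_end, seed = 17)
  post <- pre + 0.003
  b1 <- bin_trial_spikes(pre, tr)
  b2 <- bin_trial_spikes(post, tr)
  r <- ccg(b1, b2)
  expect_equal(r$lags_s[which.max(r$ccg_raw)], 0.003)
})

test_that("jitter correction nulls stimulus-locked comodulation", {
  # both units driven by the same trial-locked rate step (no spike-level
  # coupling): corrected CCG should be flat around zero
  tr <- make_trials(150, spacing = 4)
  gen <- function(seed) {
    set.seed(seed)
    st <- poisson_train(4, max(tr$auditory_onset_s) + 1)
    extra <- lapply(tr$whisker_onset_s, function(w0)
      sort(runif(rpois(1, 30 * 0.1), w0, w0 + 0.1)))
    sort(c(st, unlist(extra)))
  }
  b1 <- bin_trial_spikes(gen(19), tr)
  b2 <- bin_trial_spikes(gen(23), tr)
  jc <- jitter_correct(b1, b2, n_resamples = 50, seed = 3)
  # raw CCG is visibly elevated by the comodulation near zero lag
  near <- abs(jc$lags_s) <= 0.05
  expect_gt(mean(jc$ccg_raw[near]), 1.02)
  # corrected CCG centred on zero
  fl <- abs(jc$lags_s) >= 0.05
  expect_lt(abs(mean(jc$ccg_corrected[near])),
            3 * sd(jc$ccg_corrected[fl]) / sqrt(sum(near)) + 0.02)
  d <- detect_connection(jc)
  expect_false(d$detected)
})

test_that("an injected synapse survives jitter correction and is detected", {
  tr <- make_trials(200, spacing = 4)
  t_end <- max(tr$auditory_onset_s) + 1
  pre <- poisson_train(10, t_end, seed = 29)
  syn <- inject_connection(pre, efficacy = 0.2, delay_ms = 3,
                           jitter_ms = 0.3, seed = 31)
  post <- sort(unique(c(poisson_train(8, t_end, seed = 37), syn)))
  b1 <- bin_trial_spikes(pre, tr)
  b2 <- bin_trial_spikes(post, tr)
  jc <- jitter_correct(b1, b2, n_resamples = 100, seed = 5)
  d <- detect_connection(jc)
  expect_true(d$detected)
  expect_equal(d$peak_lag_s, 0.003, tolerance = 1e-9)
  # directionality: swapped pair shows the mirrored peak at -3 ms
  jc_rev <- jitter_correct(b2, b1, n_resamples = 100, seed = 5)
  mirror <- jc_rev$ccg_corrected[abs(jc_rev$lags_s + 0.003) < 1e-9]
  expect_gt(mirror, 6 * detect_connection(jc_rev)$flank_sd)
  expect_false(detect_connection(jc_rev)$detected)
})

test_that("detection thresholds behave on constructed corrected CCGs", {
  lags <- seq(-0.1, 0.1, by = 0.001)
  corr <- rnorm(length(lags), sd = 0.1)
  corr[abs(lags) <= 0.049] <- 0
  corr[abs(lags - 0.003) < 1e-9] <- 10 * sd(corr[abs(lags) >= 0.05])
  d <- detect_connection(corr, lags_s = lags)
  expect_true(d$detected)
  expect_equal(d$peak_lag_s, 0.003)
  # degenerate zero-variance flanks
  d0 <- detect_connection(rep(0, length(lags)), lags_s = lags)
  expect_false(d0$detected)
  expect_true(d0$degenerate)
})

test_that("pearson helpers handle the documented cases", {
  v <- c(1, 5, 3, 8, 2)
  expect_equal(pairwise_pearson(v, v), 1)
  expect_equal(pairwise_pearson(v, -v), -1)
  expect_equal(round(pairwise_pearson(c(1, 2, 3), c(2, 4, 6.1)), 5),
               round(cor(c(1, 2, 3), c(2, 4, 6.1)), 5))
  expect_gt(pairwise_pearson(c(1, 2, 3), c(2, 4, 6.1)), 0.9999)
  expect_warning(r <- pairwise_pearson(c(1, 1, 1), v[1:3]), "constant")
  expect_true(is.na(r))
  expect_error(pairwise_pearson(1:2, 1:2), "at least 3")
  # population reduction: one unit per area equals the pairwise value
  a <- list(c(1, 4, 2, 6)); b <- list(c(2, 3, 1, 5))
  expect_equal(population_pearson(a, b),
               pairwise_pearson(a[[1]], b[[1]]))
  # shared additive trial gain induces positive correlation
  set.seed(41)
  gain <- rnorm(60, sd = 3)
  ra <- lapply(1:5, function(i) gain + rnorm(60))
  rb <- lapply(1:5, function(i) gain + rnorm(60))
  expect_gt(population_pearson(ra, rb), 0.5)
})

test_that("low-rate units are flagged for Pearson exclusion", {
  tr <- make_trials(20)
  # one spike in one trial's 50-ms window: mean rate 1 Hz < 2.5 Hz
  st <- tr$whisker_onset_s[1] + 0.02
  v <- trial_response_vector(st, tr, c(0.005, 0.055))
  expect_false(attr(v, "included"))
  expect_equal(v[1], 20)  # 1 spike / 50 ms on that trial
  # sustained 60 Hz unit passes
  st2 <- sort(as.vector(outer(seq(0.006, 0.054, by = 0.016),
                              tr$whisker_onset_s, "+")))
  expect_true(attr(trial_response_vector(st2, tr, c(0.005, 0.055)),
                   "included"))
})
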