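# independent enumeration oracle for the paired sign-flip test
enumerate_paired_p <- function(d, alternative) {
  n <- length(d)
  obs <- mean(d)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- as.vector(flips %*% d) / n
  switch(alternative,
         "two-sided" = mean(abs(null) >= abs(obs)),
         greater = mean(null >= obs),
         less = mean(null <= obs))
}

test_that("paired permutation test matches exhaustive enumeration", {
  expect_equal(permutation_test_paired(rep(1, 5),
                                       alternative = "greater")$p_value,
               1 / 32)
  expect_equal(permutation_test_paired(rep(1, 5))$p_value, 2 / 32)
  set.seed(3)
  for (i in 1:20) {
    d <- round(rnorm(sample(3:10, 1)), 2)
    alt <- sample(c("two-sided", "greater", "less"), 1)
    expect_equal(permutation_test_paired(d, alternative = alt)$p_value,
                 enumerate_paired_p(d, alt), label = paste("case", i))
  }
  expect_warning(p0 <- permutation_test_paired(rep(0, 4)), "zero")
  expect_equal(p0$p_value, 1)
  expect_error(permutation_test_paired(NA_real_), "non-missing")
})

test_that("unpaired permutation test matches exhaustive enumeration", {
  # all C(6,3)=20 labelings; only the original split and its mirror are
  # as extreme as |mean(a)-mean(b)| = 10
  r <- permutation_test_unpaired(c(10, 11, 12), c(0, 1, 2))
  expect_equal(r$p_value, 2 / 20)
  expect_true(r$exhaustive)
  # independent full enumeration for a second case
  a <- c(3.2, 1.1, 4.0, 2.2); b <- c(0.5, 1.0)
  pool <- c(a, b)
  idx <- utils::combn(6, 4)
  null <- apply(idx, 2, function(k)
    mean(pool[k]) - mean(pool[-k]))
  obs <- mean(a) - mean(b)
  expect_equal(permutation_test_unpaired(a, b)$p_value,
               mean(abs(null) >= abs(obs)))
  # identical constant groups
  expect_equal(permutation_test_unpaired(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(permutation_test_unpaired(numeric(0), 1:3), "non-empty")
  # swapping groups flips the statistic, keeps the p-value
  r1 <- permutation_test_unpaired(a, b)
  r2 <- permutation_test_unpaired(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("permutation tests are calibrated under the null", {
  # exhaustive sign-flip on n=10 N(0,1) draws, 1000 replicates:
  # rejection rate at alpha = 0.05 within the binomial 99% CI
  set.seed(29)
  alpha <- 0.05
  rej <- vapply(1:1000, function(i) {
    d <- rnorm(10)
    permutation_test_paired(d)$p_value <= alpha
  }, logical(1))
  ci_half <- qnorm(0.995) * sqrt(alpha * (1 - alpha) / 1000)
  expect_lt(abs(mean(rej) - alpha), ci_half + 1e-12)
})

test_that("Monte Carlo p-values are reproducible given the seed", {
  d <- rnorm(30)
  p1 <- permutation_test_paired(d, n_perm = 500, seed = 42)$p_value
  p2 <- permutation_test_paired(d, n_perm = 500, seed = 42)$p_value
  expect_identical(p1, p2)
  g <- rnorm(25)
  q1 <- permutation_test_unpaired(d, g, n_perm = 500, seed = 7)$p_value
  q2 <- permutation_test_unpaired(d, g, n_perm = 500, seed = 7)$p_value
  expect_identical(q1, q2)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  # hand computation: p_(i) * m / i, cumulative minimum from the top
  p <- c(0.005, 0.009, 0.05, 0.5)
  hand <- c(0.018, 0.018, 2 / 30, 0.5)
  expect_equal(fdr_adjust(p), hand)
  # monotone in the input order statistics
  set.seed(5)
  p <- runif(50)
  q <- fdr_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q <= 1))
})

test_that("BH controls FDR at level alpha under independence", {
  # m = 100 true nulls per replicate; any rejection is a false discovery,
  # so FDR = P(reject any) estimated over replicates
  set.seed(31)
  alpha <- 0.1
  n_rep <- 1000
  fdp <- vapply(seq_len(n_rep), function(i) {
    q <- fdr_adjust(runif(100))
    r <- sum(q <= alpha)
    if (r == 0) 0 else 1  # all discoveries are false under the global null
  }, 0)
  mc_se <- sd(fdp) / sqrt(n_rep)
  expect_lte(mean(fdp), alpha + 2 * mc_se)
})

test_that("chi-squared proportion test reproduces printed and hand values", {
  r <- chi2_proportion_test(3, 1077, 17, 1066)
  expect_equal(signif(r$p_value, 2), 0.0032)
  eq <- chi2_proportion_test(5, 100, 5, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # hand Yates computation: pooled p = 0.5, |O-E| = 5 everywhere,
  # chi2 = 4 * (5 - 0.5)^2 / 5 = 16.2
  expect_equal(chi2_proportion_test(0, 10, 10, 10)$statistic, 16.2)
  # symmetric under swapping groups
  a <- chi2_proportion_test(7, 120, 19, 140)
  b <- chi2_proportion_test(19, 140, 7, 120)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_error(chi2_proportion_test(1, 0, 1, 5), "> 0")
  expect_error(chi2_proportion_test(6, 5, 1, 5), "0 <= k <= n")
})
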