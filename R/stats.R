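#' @importFrom stats sd rnorm rpois runif rbinom rlnorm quantile p.adjust
#'   prop.test cor setNames complete.cases
NULL

.perm_p <- function(obs, null_stats, alternative, exhaustive) {
  n <- length(null_stats)
  hits <- switch(alternative,
    "two-sided" = sum(abs(null_stats) >= abs(obs)),
    greater = sum(null_stats >= obs),
    less = sum(null_stats <= obs))
  if (exhaustive) hits / n else (1 + hits) / (1 + n)
}

.new_test_result <- function(statistic, p, n_perm, alternative, seed,
                             method, exhaustive = FALSE) {
  structure(list(statistic = statistic, p_value = p, n_permutations = n_perm,
                 alternative = alternative, seed = seed, method = method,
                 exhaustive = exhaustive),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, %s%d permutations)\n",
              x$method, x$statistic, x$p_value, x$alternative,
              if (x$exhaustive) "exhaustive " else "", x$n_permutations))
  invisible(x)
}

#' Paired nonparametric permutation test
#'
#' Tests whether the mean of paired differences is zero by randomly flipping
#' the sign of each difference. When `2^n <= n_perm` the full sign-flip null
#' distribution is enumerated and the p-value is the exact tail proportion;
#' otherwise `n_perm` random flips are drawn and the add-one formula
#' `(1 + hits) / (1 + n_perm)` keeps the p-value away from zero.
#'
#' @param differences numeric vector of paired differences (NAs dropped).
#' @param n_perm number of permutations.
#' @param seed integer seed for the random draws.
#' @param alternative `"two-sided"`, `"greater"` or `"less"`.
#' @return a `perm_test_result` with fields `statistic` (mean difference),
#'   `p_value`, `n_permutations`, `alternative`, `seed`.
#' @export
permutation_test_paired <- function(differences, n_perm = 10000,
                                    seed = 1,
                                    alternative = c("two-sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  d <- differences[!is.na(differences)]
  if (length(d) == 0) stop("permutation_test_paired: no non-missing differences")
  obs <- mean(d)
  if (all(d == 0)) {
    warning("all differences are zero; p = 1")
    return(.new_test_result(0, 1, 0L, alternative, seed, "paired permutation"))
  }
  n <- length(d)
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_stats <- as.vector(signs %*% d) / n
    p <- .perm_p(obs, null_stats, alternative, exhaustive = TRUE)
    return(.new_test_result(obs, p, nrow(signs), alternative, seed,
                            "paired permutation", exhaustive = TRUE))
  }
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n_perm)
  null_stats <- as.vector(signs %*% d) / n
  p <- .perm_p(obs, null_stats, alternative, exhaustive = FALSE)
  .new_test_result(obs, p, n_perm, alternative, seed, "paired permutation")
}

#' Unpaired nonparametric permutation test
#'
#' Tests for a difference in group means by shuffling group labels. The
#' statistic is `mean(group_a) - mean(group_b)`. The full set of labelings is
#' enumerated when `choose(n, n_a) <= n_perm`, giving an exact p-value;
#' otherwise random shuffles with the add-one formula are used.
#'
#' @param group_a,group_b numeric vectors (NAs dropped).
#' @inheritParams permutation_test_paired
#' @return a `perm_test_result`.
#' @export
permutation_test_unpaired <- function(group_a, group_b, n_perm = 10000,
                                      seed = 1,
                                      alternative = c("two-sided", "greater",
                                                      "less")) {
  alternative <- match.arg(alternative)
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) == 0 || length(b) == 0)
    stop("permutation_test_unpaired: both groups must be non-empty")
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  obs <- mean(a) - mean(b)
  tot <- sum(pool)
  stat_from_asum <- function(sa) sa / na - (tot - sa) / (n - na)
  n_comb <- choose(n, na)
  if (is.finite(n_comb) && n_comb <= n_perm) {
    idx <- utils::combn(n, na)
    null_stats <- stat_from_asum(colSums(matrix(pool[idx], nrow = na)))
    p <- .perm_p(obs, null_stats, alternative, exhaustive = TRUE)
    return(.new_test_result(obs, p, as.integer(n_comb), alternative, seed,
                            "unpaired permutation", exhaustive = TRUE))
  }
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    sa <- sum(pool[sample.int(n, na)])
    stat_from_asum(sa)
  }, 0)
  p <- .perm_p(obs, null_stats, alternative, exhaustive = FALSE)
  .new_test_result(obs, p, n_perm, alternative, seed, "unpaired permutation")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values; rejecting `q <= alpha` controls the false
#' discovery rate at `alpha` under independence.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values of the same length (empty input gives empty output).
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop("fdr_adjust: p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Chi-squared test of equal proportions
#'
#' 2x2 chi-squared comparison of `k1/n1` versus `k2/n2` with Yates continuity
#' correction, as used for comparing counts of modulated neurons or detected
#' connections between groups.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @return a `perm_test_result`-style list with `statistic` (chi-squared) and
#'   two-sided `p_value`.
#' @export
chi2_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("chi2_proportion_test: group sizes must be > 0")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("chi2_proportion_test: counts must satisfy 0 <= k <= n")
  ht <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2),
                                          correct = TRUE))
  .new_test_result(unname(ht$statistic), ht$p.value, 0L, "two-sided", NA,
                   "chi-squared proportion test (Yates)")
}
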