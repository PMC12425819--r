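test_that("fisher_2x2 reproduces hand-enumerated and published p-values", {
  # perfectly balanced table
  expect_equal(fisher_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # hand enumeration: [[1,9],[9,1]] two-sided = 202/184756
  expect_equal(fisher_2x2(matrix(c(1, 9, 9, 1), 2, byrow = TRUE))$p_value,
               202 / 184756, tolerance = 1e-12)
  # discovery-cohort PIK3CA counts: 3/21 vs 266/554
  res <- fisher_2x2(matrix(c(3, 18, 266, 288), 2, byrow = TRUE))
  expect_equal(signif(res$p_value, 1), 0.003)
  expect_error(fisher_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("fisher_2x2 agrees with stats::fisher.test and the enumeration oracle", {
  set.seed(42)
  for (i in 1:150) {
    tab <- matrix(rpois(4, sample(1:30, 1)), 2)
    for (sided in c("two_sided", "less", "greater")) {
      mine <- fisher_2x2(tab, sided)$p_value
      expect_equal(mine, oracle_fisher_p(tab, sided), tolerance = 1e-10)
      alt <- c(two_sided = "two.sided", less = "less", greater = "greater")[sided]
      expect_equal(mine, fisher.test(tab, alternative = alt)$p.value,
                   tolerance = 1e-7)
    }
  }
})

test_that("odds ratio follows the sample (a*d)/(b*c) convention with zero-cell rules", {
  expect_equal(fisher_2x2(matrix(c(4, 2, 3, 6), 2, byrow = TRUE))$odds_ratio, 4)
  expect_equal(fisher_2x2(matrix(c(4, 0, 3, 6), 2, byrow = TRUE))$odds_ratio, Inf)
  expect_equal(fisher_2x2(matrix(c(0, 4, 3, 6), 2, byrow = TRUE))$odds_ratio, 0)
})

test_that("Monte Carlo r x c test matches full enumeration and is reproducible", {
  tab <- matrix(c(5, 0, 0, 0, 5, 5), 2, byrow = TRUE)
  exact <- oracle_rxc_exact(tab)
  res <- fisher_rxc_mc(tab, iterations = 2e5, seed = 7)
  expect_lt(abs(res$p_value - exact), 3 * res$mc_se + 1e-6)
  expect_equal(res$p_value, fisher_rxc_mc(tab, iterations = 2e5, seed = 7)$p_value)

  # a second table with nontrivial margins
  tab2 <- matrix(c(3, 1, 4, 1, 6, 2), 2, byrow = TRUE)
  res2 <- fisher_rxc_mc(tab2, iterations = 2e5, seed = 11)
  expect_lt(abs(res2$p_value - oracle_rxc_exact(tab2)), 3 * res2$mc_se + 1e-6)

  # one nonzero row -> degenerate margins, P = 1
  expect_equal(fisher_rxc_mc(matrix(c(2, 3, 4, 0, 0, 0), 2, byrow = TRUE),
                             iterations = 10, seed = 1)$p_value, 1)
  # 2x2 input delegates to the exact test
  expect_message(
    d <- fisher_rxc_mc(matrix(c(3, 18, 266, 288), 2, byrow = TRUE), seed = 1),
    "exact"
  )
  expect_equal(d$method, "fisher_exact")
})

test_that("bh_adjust reproduces the step-up formula and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  q <- bh_adjust(c(0.0009, 0.003, 0.5, 0.7, 0.9))
  expect_equal(q[1:2], c(0.0045, 0.0075))
  expect_true(all(q >= c(0.0009, 0.003, 0.5, 0.7, 0.9)))
  # monotone in p and permutation-equivariant
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("beta_sd matches the closed form, numeric integration and symmetry", {
  expect_equal(beta_sd(0, 0), sqrt(1 / 12))
  expect_equal(beta_sd(3, 21), sqrt(76 / 12696))
  expect_equal(beta_sd(3, 21), beta_sd(18, 21))
  # numeric integration oracle
  for (kn in list(c(0, 5), c(3, 21), c(10, 10))) {
    k <- kn[1]; n <- kn[2]
    mom <- function(r) {
      integrate(function(x) x^r * dbeta(x, k + 1, n - k + 1), 0, 1,
                rel.tol = 1e-12)$value
    }
    expect_equal(beta_sd(k, n), sqrt(mom(2) - mom(1)^2), tolerance = 1e-10)
  }
  expect_error(beta_sd(5, 3), "k <= n")
})

test_that("stratified_fisher convolves strata and excludes zero-marginal tables", {
  s1 <- matrix(c(2, 0, 0, 2), 2, byrow = TRUE)
  # two perfectly concordant strata: P = 2/36
  expect_equal(stratified_fisher(list(s1, s1))$p_value, 2 / 36, tolerance = 1e-12)
  # one stratum reduces exactly to fisher_2x2
  tab <- matrix(c(3, 18, 266, 288), 2, byrow = TRUE)
  for (sided in c("two_sided", "less", "greater")) {
    expect_equal(stratified_fisher(list(tab), sided)$p_value,
                 fisher_2x2(tab, sided)$p_value, tolerance = 1e-12)
  }
  # zero-marginal stratum is a no-op
  zero_col <- matrix(c(0, 4, 0, 6), 2, byrow = TRUE)
  expect_message(
    res <- stratified_fisher(list(s1, s1, zero_col)),
    "zero-marginal"
  )
  expect_equal(res$p_value, 2 / 36, tolerance = 1e-12)
  expect_equal(res$n_strata_dropped, 1)
  expect_error(suppressMessages(stratified_fisher(list(zero_col))),
               "no informative strata")
})

test_that("cooccurrence cross-tabulates and is calibrated at independence", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  res <- cooccurrence(a, a)
  expect_equal(res$odds_ratio, Inf)
  expect_equal(res$p_value, oracle_fisher_p(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)))
  expect_error(cooccurrence(c(TRUE), c(TRUE, FALSE)), "length")

  # independence: rejection rate bounded by alpha (exact test is conservative)
  set.seed(99)
  reject <- vapply(1:300, function(i) {
    x <- runif(60) < 0.3
    y <- runif(60) < 0.3
    cooccurrence(x, y)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(reject), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("planted mutual exclusivity yields odds ratios below 1", {
  # joint cell probabilities for binary (A, B) at a target odds ratio
  joint_or <- function(pa, pb, theta) {
    s <- 1 + (pa + pb) * (theta - 1)
    p11 <- if (theta == 1) pa * pb else {
      (s - sqrt(s^2 - 4 * theta * (theta - 1) * pa * pb)) / (2 * (theta - 1))
    }
    c(p11 = p11, p10 = pa - p11, p01 = pb - p11, p00 = 1 - pa - pb + p11)
  }
  probs <- joint_or(0.2, 0.45, 0.2)
  set.seed(7)
  below <- vapply(1:100, function(i) {
    cell <- sample(1:4, 577, TRUE, prob = probs)
    res <- cooccurrence(cell %in% c(1, 2), cell %in% c(1, 3))
    is.finite(res$odds_ratio) && res$odds_ratio < 1
  }, logical(1))
  expect_gte(mean(below), 0.95)
})

test_that("rank_sum uses the exact distribution for tiny samples and handles ties", {
  expect_equal(rank_sum(c(1, 2), c(3, 4), "less")$p_value, 1 / 6)
  # identical multisets -> P = 1 under the approximation
  same <- rank_sum(c(1, 2, 3, 1, 2, 3, 4, 5, 6), c(1, 2, 3, 1, 2, 3, 4, 5, 6))
  expect_equal(same$p_value, 1, tolerance = 0.05)
  # degenerate all-equal input
  expect_equal(rank_sum(c(2, 2), c(2, 2))$p_value, 1)
  # shift invariance
  x <- c(3, 1, 4, 1, 5); y <- c(9, 2, 6, 5, 3.5)
  expect_equal(rank_sum(x + 10, y + 10)$p_value, rank_sum(x, y)$p_value)
  expect_equal(unname(rank_sum(x, y)$medians), c(median(x), median(y)))
  expect_error(rank_sum(numeric(0), 1), "empty")
})

test_that("shift_compare shifts the first group before the rank-sum test", {
  x <- c(0, 1, 1, 2); y <- c(1, 2, 2, 3)
  expect_equal(shift_compare(x, y, 0)$p_value, rank_sum(x, y)$p_value)
  expect_equal(shift_compare(c(1, 1), c(2, 2), 1)$p_value, 1)
  expect_error(shift_compare(x, y, -1), ">= 0")

  # true difference of exactly one event: the +1 comparison is nonsignificant
  set.seed(3)
  nonsig <- vapply(1:50, function(i) {
    xc <- rpois(21, 1)
    yc <- rpois(554, 1) + 1
    shift_compare(xc, yc, 1)$p_value > 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.9)
})

test_that("pearson_corr matches the covariance-ratio formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_corr(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_corr(x, -x)$statistic, -1)
  y <- c(2.1, 1.9, 3.5, 2.8, 4.4)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_corr(x, y)$statistic, r_manual, tolerance = 1e-12)
  expect_error(pearson_corr(c(1, 1, 1), y[1:3]), "variance")
  expect_error(pearson_corr(1:2, 2:3), "at least 3")
})

test_that("test results tidy into one-row tibbles", {
  td <- tidy(fisher_2x2(matrix(c(3, 18, 266, 288), 2, byrow = TRUE)))
  expect_equal(nrow(td), 1)
  expect_named(td, c("method", "sidedness", "p_value", "statistic",
                     "odds_ratio", "mc_iterations", "mc_se"))
  expect_equal(td$method, "fisher_exact")
})
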