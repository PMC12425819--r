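# Exact and resampling statistics: Fisher tests (probability-mass two-sided
# convention), Monte Carlo r x c Fisher, BH correction, beta-distribution
# frequency uncertainty, exact-conditional stratified tests, co-occurrence
# odds ratios, rank-sum / shift comparisons and Pearson correlation.

# relative tolerance when comparing point probabilities, to absorb
# floating-point ties in the probability-mass two-sided rule
PM_TOL <- 1 + 1e-7

#' Labeled contingency table
#'
#' @param counts Matrix of nonnegative integers, at least 2x2.
#' @param row_labels,col_labels Optional dimension labels.
#' @return Object of class `contingency_table` (an integer matrix).
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("contingency_table: entries must be nonnegative integers")
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("contingency_table: need at least a 2x2 table")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  structure(counts, class = c("contingency_table", class(counts)))
}

as_2x2 <- function(table) {
  m <- unclass(as.matrix(table))
  if (!all(dim(m) == c(2, 2))) abort("expected a 2x2 table")
  if (any(m < 0)) abort("table entries must be nonnegative")
  if (any(m != round(m))) abort("table entries must be integers")
  storage.mode(m) <- "double"
  m
}

new_test_result <- function(p_value, method, sidedness, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    c(list(
      p_value = min(p_value, 1), method = method, sidedness = sidedness
    ), list(...)),
    class = "mut_test"
  )
}

#' @export
print.mut_test <- function(x, ...) {
  cat(sprintf("<mut_test> %s (%s): P = %.4g", x$method, x$sidedness, x$p_value))
  if (!is.null(x$odds_ratio)) cat(sprintf(", OR = %.3g", x$odds_ratio))
  if (!is.null(x$statistic)) cat(sprintf(", statistic = %.4g", x$statistic))
  cat("\n")
  invisible(x)
}

#' @export
tidy.mut_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    sidedness = x$sidedness,
    p_value = x$p_value,
    statistic = x$statistic %||% NA_real_,
    odds_ratio = x$odds_ratio %||% NA_real_,
    mc_iterations = x$mc_iterations %||% NA_real_,
    mc_se = x$mc_se %||% NA_real_
  )
}

#' @export
glance.mut_test <- function(x, ...) tidy(x, ...)

match_sidedness <- function(sidedness) {
  match.arg(sidedness, c("two_sided", "less", "greater"))
}

# hypergeometric pmf over the full allocation support of a 2x2 table with
# margins (n1, n2 | m): returns list(support, pmf) where 'a' counts
# successes in group 1
hyper_pmf_2x2 <- function(n1, n2, m) {
  lo <- max(0L, m - n2)
  hi <- min(m, n1)
  support <- lo:hi
  pmf <- dhyper(support, m, n1 + n2 - m, n1)
  list(support = support, pmf = pmf / sum(pmf))
}

# Fisher p-value for all allocations at once given fixed margins.
# Returns a vector aligned with the support.
fisher_p_all_allocations <- function(n1, n2, m, sidedness) {
  h <- hyper_pmf_2x2(n1, n2, m)
  switch(sidedness,
    two_sided = vapply(h$pmf, function(p0) {
      keep <- h$pmf <= p0 * PM_TOL
      if (all(keep)) 1 else sum(h$pmf[keep])
    }, numeric(1)),
    less = cumsum(h$pmf),
    greater = rev(cumsum(rev(h$pmf)))
  )
}

sample_odds_ratio <- function(m) {
  num <- m[1, 1] * m[2, 2]
  den <- m[1, 2] * m[2, 1]
  if (den == 0 && num == 0) return(NaN)
  if (den == 0) return(Inf)
  num / den
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on a 2x2 table laid out as groups in rows and
#' (success, failure) in columns. The two-sided p-value follows the
#' probability-mass convention: the sum of point probabilities of all
#' allocations no more probable than the observed one (with a small relative
#' tolerance for floating-point ties), matching [stats::fisher.test()]. The
#' odds ratio is the unconditional sample estimate `(a*d)/(b*c)`; a zero
#' denominator gives `Inf` (or `NaN` when the numerator is also zero).
#'
#' @param table 2x2 matrix or [contingency_table()]; rows are groups,
#'   column 1 counts successes (e.g. mutated samples).
#' @param sidedness `"two_sided"` (default), `"less"` (deficiency in the
#'   first row) or `"greater"`.
#' @return A `mut_test` with `p_value` and `odds_ratio`.
#' @examples
#' fisher_2x2(matrix(c(3, 18, 266, 288), 2, byrow = TRUE))
#' @export
fisher_2x2 <- function(table, sidedness = "two_sided") {
  sidedness <- match_sidedness(sidedness)
  m <- as_2x2(table)
  n1 <- sum(m[1, ])
  n2 <- sum(m[2, ])
  mm <- sum(m[, 1])
  h <- hyper_pmf_2x2(n1, n2, mm)
  a <- m[1, 1]
  idx <- match(a, h$support)
  p <- fisher_p_all_allocations(n1, n2, mm, sidedness)[idx]
  new_test_result(
    p_value = p,
    method = "fisher_exact",
    sidedness = sidedness,
    odds_ratio = sample_odds_ratio(m),
    table = m
  )
}

# log point-probability of an r x c table under fixed margins
log_prob_rxc <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Monte Carlo Fisher test for r x c tables
#'
#' Estimates the exact conditional p-value of an r x c table by sampling
#' tables with the observed margins ([stats::r2dtable()]) and counting those
#' whose point probability does not exceed the observed one. The add-one
#' estimator `(1 + hits) / (iterations + 1)` is used so the estimate is never
#' zero. 2x2 input is delegated to [fisher_2x2()] with a notice.
#'
#' @param table r x c matrix of nonnegative integers.
#' @param iterations Number of Monte Carlo tables (default 1e6).
#' @param seed Integer seed; recorded in the result.
#' @return A `mut_test` with `p_value`, `mc_iterations`, `mc_se` and `seed`.
#' @export
fisher_rxc_mc <- function(table, iterations = 1e6, seed = 1L) {
  m <- unclass(as.matrix(table))
  if (any(m < 0) || any(m != round(m))) {
    abort("fisher_rxc_mc: entries must be nonnegative integers")
  }
  if (all(dim(m) == c(2, 2))) {
    inform("2x2 table: using the exact 2x2 test instead of Monte Carlo")
    return(fisher_2x2(m))
  }
  rs <- rowSums(m)
  cs <- colSums(m)
  if (sum(rs > 0) < 2 || sum(cs > 0) < 2) {
    # degenerate margins: only one table is possible
    return(new_test_result(
      p_value = 1, method = "fisher_mc", sidedness = "two_sided",
      mc_iterations = 0, mc_se = 0, seed = seed
    ))
  }
  log_obs <- log_prob_rxc(m)
  hits <- withr::with_seed(seed, {
    total <- 0
    remaining <- iterations
    chunk <- 100000L
    while (remaining > 0) {
      k <- min(chunk, remaining)
      tabs <- r2dtable(k, rs, cs)
      lp <- vapply(tabs, log_prob_rxc, numeric(1))
      total <- total + sum(lp <= log_obs + log(PM_TOL))
      remaining <- remaining - k
    }
    total
  })
  p <- (1 + hits) / (iterations + 1)
  new_test_result(
    p_value = p, method = "fisher_mc", sidedness = "two_sided",
    mc_iterations = iterations,
    mc_se = sqrt(p * (1 - p) / iterations),
    seed = seed
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper around
#' [stats::p.adjust()] that keeps input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order, with `q >= p` elementwise.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("bh_adjust: p-values must be in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Beta-distribution standard deviation of an observed frequency
#'
#' The uncertainty attached to an observed mutation frequency `k/n`:
#' the standard deviation of `Beta(k + 1, n - k + 1)`, the posterior of the
#' frequency under a uniform prior.
#'
#' @param k Number of mutated samples (vectorized).
#' @param n Cohort size.
#' @return Standard deviation(s) in (0, 0.5].
#' @examples
#' beta_sd(3, 21)
#' @export
beta_sd <- function(k, n) {
  if (any(k < 0) || any(k > n) || any(n < 0)) {
    abort("beta_sd: need 0 <= k <= n")
  }
  a <- k + 1
  b <- n - k + 1
  sqrt(a * b / ((a + b)^2 * (a + b + 1)))
}

#' Frequency estimate with beta-distribution uncertainty
#'
#' @param k Mutated count(s).
#' @param n Cohort size(s).
#' @return Tibble with `k`, `n`, `freq`, `beta_a`, `beta_b`, `sd`.
#' @export
freq_estimate <- function(k, n) {
  tibble::tibble(
    k = k, n = n, freq = k / n,
    beta_a = k + 1, beta_b = n - k + 1,
    sd = beta_sd(k, n)
  )
}

has_zero_margin <- function(m) {
  any(rowSums(m) == 0) || any(colSums(m) == 0)
}

#' Exact conditional stratified Fisher test
#'
#' Combines 2x2 tables across strata while conditioning on every stratum's
#' margins: the test statistic is the total number of successes in group 1
#' across strata, and its null distribution is the convolution of the
#' per-stratum central hypergeometric distributions. Strata with a zero row
#' or column margin are uninformative and dropped (with a message). The
#' two-sided p-value uses the same probability-mass rule as [fisher_2x2()],
#' to which this test reduces for a single stratum.
#'
#' @param tables List of 2x2 matrices/[contingency_table()]s, one per stratum.
#' @param sidedness `"two_sided"`, `"less"` or `"greater"`.
#' @return A `mut_test` with `p_value`, `statistic` (observed total) and the
#'   numbers of strata used and dropped.
#' @export
stratified_fisher <- function(tables, sidedness = "two_sided") {
  sidedness <- match_sidedness(sidedness)
  if (length(tables) == 0) abort("stratified_fisher: need at least one stratum")
  mats <- lapply(tables, as_2x2)
  keep <- !vapply(mats, has_zero_margin, logical(1))
  if (sum(!keep) > 0) {
    inform(sprintf(
      "stratified_fisher: dropped %d zero-marginal stratum/strata", sum(!keep)
    ))
  }
  mats <- mats[keep]
  if (length(mats) == 0) abort("stratified_fisher: no informative strata")

  # convolve per-stratum hypergeometric pmfs of the group-1 success count
  s_obs <- sum(vapply(mats, function(m) m[1, 1], numeric(1)))
  pmf <- c(1)
  offset <- 0
  for (m in mats) {
    n1 <- sum(m[1, ])
    n2 <- sum(m[2, ])
    mm <- sum(m[, 1])
    h <- hyper_pmf_2x2(n1, n2, mm)
    new_pmf <- numeric(length(pmf) + length(h$pmf) - 1)
    for (i in seq_along(h$pmf)) {
      idx <- seq_along(pmf) + i - 1
      new_pmf[idx] <- new_pmf[idx] + pmf * h$pmf[i]
    }
    pmf <- new_pmf
    offset <- offset + h$support[1]
  }
  support <- offset + seq_along(pmf) - 1
  obs_idx <- match(s_obs, support)
  p_obs <- pmf[obs_idx]
  p <- switch(sidedness,
    two_sided = sum(pmf[pmf <= p_obs * PM_TOL]),
    less = sum(pmf[support <= s_obs]),
    greater = sum(pmf[support >= s_obs])
  )
  new_test_result(
    p_value = p, method = "stratified_fisher_exact", sidedness = sidedness,
    statistic = s_obs,
    n_strata_used = length(mats),
    n_strata_dropped = sum(!keep)
  )
}

#' Co-occurrence / mutual-exclusivity test for two gene indicators
#'
#' Cross-tabulates two per-sample mutation indicator vectors and applies the
#' two-sided exact test; the odds ratio is the sample estimate, with OR < 1
#' indicating mutual exclusivity and OR > 1 co-occurrence.
#'
#' @param a,b Logical vectors of equal length (one entry per sample).
#' @return A `mut_test` with `p_value`, `odds_ratio` and the 2x2 `table`.
#' @export
cooccurrence <- function(a, b) {
  if (length(a) != length(b)) abort("cooccurrence: length mismatch")
  a <- as.logical(a)
  b <- as.logical(b)
  tab <- matrix(
    c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
    2, 2, byrow = TRUE,
    dimnames = list(c("a_mut", "a_wt"), c("b_mut", "b_wt"))
  )
  res <- fisher_2x2(tab)
  res$method <- "cooccurrence_fisher"
  res
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Exact null distribution when the smaller sample has at most 8 values and
#' there are no ties; otherwise the normal approximation with tie correction
#' and continuity correction. When the pooled values are all identical the
#' p-value is 1 by convention (the null distribution is degenerate).
#'
#' @param x,y Numeric vectors, both nonempty.
#' @param sidedness `"two_sided"`, `"less"` or `"greater"` (alternative for
#'   `x` relative to `y`).
#' @return A `mut_test` with `p_value`, `statistic` (rank-sum W) and the two
#'   group medians in `medians`.
#' @export
rank_sum <- function(x, y, sidedness = "two_sided") {
  sidedness <- match_sidedness(sidedness)
  if (length(x) == 0 || length(y) == 0) abort("rank_sum: empty input")
  alternative <- switch(sidedness,
    two_sided = "two.sided", less = "less", greater = "greater"
  )
  pooled <- c(x, y)
  if (var(pooled) == 0 || length(unique(pooled)) == 1) {
    return(new_test_result(
      p_value = 1, method = "wilcoxon_rank_sum", sidedness = sidedness,
      statistic = unname(suppressWarnings(
        wilcox.test(x, y, exact = FALSE)$statistic
      )),
      medians = c(x = median(x), y = median(y))
    ))
  }
  use_exact <- min(length(x), length(y)) <= 8 && !any(duplicated(pooled))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = use_exact, correct = TRUE)
  )
  new_test_result(
    p_value = wt$p.value,
    method = if (use_exact) "wilcoxon_rank_sum_exact" else "wilcoxon_rank_sum",
    sidedness = sidedness,
    statistic = unname(wt$statistic),
    medians = c(x = median(x), y = median(y))
  )
}

#' Rank-sum comparison after shifting the first group
#'
#' Tests whether the difference between two count distributions exceeds a
#' stated number of events by adding `shift` to every value of `x` before the
#' rank-sum comparison (e.g. "is the deficit larger than one event?").
#'
#' @param x,y Numeric (count) vectors.
#' @param shift Nonnegative integer added elementwise to `x`.
#' @param sidedness Passed to [rank_sum()].
#' @return A `mut_test`; `shift` is recorded in the result.
#' @export
shift_compare <- function(x, y, shift = 1L, sidedness = "two_sided") {
  if (shift < 0) abort("shift_compare: shift must be >= 0")
  res <- rank_sum(x + shift, y, sidedness)
  res$shift <- shift
  res$method <- "shifted_rank_sum"
  res
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A `mut_test` with `statistic` = r and a two-sided `p_value`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort("pearson_corr: length mismatch")
  if (length(x) < 3) abort("pearson_corr: need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) abort("pearson_corr: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  new_test_result(
    p_value = ct$p.value, method = "pearson", sidedness = "two_sided",
    statistic = unname(ct$estimate)
  )
}
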