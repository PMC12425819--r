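# Fixed-margin power analysis for two-cohort frequency comparisons: the
# minimal achievable Fisher p-value over all 2x2 tables sharing the observed
# margins, Bonferroni gating, the minimal detectable mutated count, and the
# full power-gated frequency comparison.

#' Minimal achievable Fisher p-value at fixed margins
#'
#' With cohort sizes `n1` and `n2` and a total of `m` mutated samples across
#' both cohorts, scans every allocation `a` of the `m` mutated samples to the
#' first cohort (all 2x2 tables with the observed margins, zero counts
#' allowed) and returns the smallest Fisher p-value any of them attains —
#' the best case in which the true effect is maximal. A comparison is
#' *powered* when this optimum survives multiple-testing correction: an
#' unpowered gene cannot reach significance no matter how extreme the data.
#'
#' @param n1,n2 Cohort sizes.
#' @param m Total mutated count across both cohorts, `0 <= m <= n1 + n2`.
#' @param sidedness `"two_sided"` (default), `"less"` or `"greater"`.
#' @return The minimal p-value (a single number in (0, 1]).
#' @examples
#' min_achievable_p(21, 554, 269)
#' @export
min_achievable_p <- function(n1, n2, m, sidedness = "two_sided") {
  sidedness <- match_sidedness(sidedness)
  if (n1 < 1 || n2 < 1) abort("min_achievable_p: cohort sizes must be >= 1")
  if (m < 0 || m > n1 + n2) abort("min_achievable_p: need 0 <= m <= n1 + n2")
  min(fisher_p_all_allocations(n1, n2, m, sidedness))
}

#' Power-gate a set of genes by their observed margins
#'
#' Applies [min_achievable_p()] to each gene's margins, Bonferroni-corrects
#' over `n_tests` hypotheses, and flags the genes whose corrected optimal
#' p-value is below `alpha` as powered. Only powered genes should then be
#' tested for frequency differences; the gate precedes testing.
#'
#' @param gene_margins Tibble/data frame with columns `gene`, `n1`, `n2`, `m`.
#' @param n_tests Bonferroni divisor (the number of genes screened, e.g. the
#'   size of the driver panel the margins came from).
#' @param alpha Significance level for the power call (default 0.05).
#' @param sidedness Sidedness of the gated test.
#' @return Tibble with `gene`, `n1`, `n2`, `m`, `min_p`, `corrected_min_p`
#'   and `powered`, sorted by `corrected_min_p`.
#' @export
powered_genes <- function(gene_margins, n_tests, alpha = 0.05,
                          sidedness = "two_sided") {
  check_required_cols(gene_margins, c("gene", "n1", "n2", "m"), "gene_margins")
  if (nrow(gene_margins) == 0) abort("powered_genes: empty gene_margins")
  if (n_tests < 1) abort("powered_genes: n_tests must be >= 1")
  gene_margins |>
    tibble::as_tibble() |>
    dplyr::mutate(
      min_p = purrr::pmap_dbl(
        list(.data$n1, .data$n2, .data$m),
        function(n1, n2, m) min_achievable_p(n1, n2, m, sidedness)
      ),
      corrected_min_p = pmin(1, .data$min_p * n_tests),
      powered = .data$corrected_min_p < alpha
    ) |>
    dplyr::arrange(.data$corrected_min_p)
}

#' Minimal detectable mutated count in the control cohort
#'
#' The smallest total mutated count `m` in the control cohort for which a
#' complete deficiency in the exposed cohort (a `[[0, n1], [m, n2 - m]]`
#' table) is significant by the one-sided Fisher test at level `alpha`.
#' Genes mutated in fewer than this many control samples can never show a
#' significant depletion at the given cohort sizes.
#'
#' @param n1 Exposed cohort size.
#' @param n2 Control cohort size.
#' @param alpha Significance level (default 0.05); the scan uses strict
#'   `P < alpha`.
#' @return The smallest qualifying `m` as an integer, or `NA` (with a
#'   message) if no count up to `n2` is detectable.
#' @examples
#' min_detectable_count(21, 554) # 76
#' @export
min_detectable_count <- function(n1, n2, alpha = 0.05) {
  if (n1 < 1 || n2 < 1) abort("min_detectable_count: cohort sizes must be >= 1")
  # one-sided (less) P for a = 0 is the hypergeometric point mass at zero,
  # which is nonincreasing in m, so the first crossing is the answer
  m <- seq_len(n2)
  p0 <- dhyper(0, m, n1 + n2 - m, n1)
  hit <- which(p0 < alpha)
  if (length(hit) == 0) {
    inform(sprintf(
      "no detectable count at n1 = %d, n2 = %d, alpha = %g", n1, n2, alpha
    ))
    return(NA_integer_)
  }
  as.integer(m[hit[1]])
}

#' Power-gated comparison of per-gene mutation frequencies
#'
#' The full comparison pipeline for two cohorts over a gene panel:
#' (1) binarize both cohorts and take each gene's observed margins;
#' (2) gate genes by [min_achievable_p()] with Bonferroni correction over
#' `n_tests`; (3) run the Fisher test at the configured sidedness for each
#' powered gene; (4) Benjamini-Hochberg correct across the powered genes.
#' Unpowered genes are reported with their frequencies but no test.
#'
#' @param exposed,control [cohort()] objects.
#' @param genes A [gene_list()].
#' @param n_tests Bonferroni divisor for the power gate.
#' @param alpha Power-gate significance level (default 0.05).
#' @param sidedness Sidedness of the per-gene Fisher tests (and the gate).
#' @param hotspot_only Passed to [binarize()].
#' @return A tibble of class `freq_comparison` with one row per gene:
#'   counts and frequencies with beta-distribution SDs for both cohorts,
#'   `min_p`, `corrected_min_p`, `powered`, and `p_value`/`q_value` for
#'   powered genes (`NA` otherwise).
#' @export
compare_gene_frequencies <- function(exposed, control, genes,
                                     n_tests = length(genes$genes),
                                     alpha = 0.05,
                                     sidedness = "two_sided",
                                     hotspot_only = FALSE) {
  stopifnot(inherits(exposed, "cohort"), inherits(control, "cohort"))
  if (length(genes$genes) == 0) abort("compare_gene_frequencies: empty gene list")
  sidedness <- match_sidedness(sidedness)
  b1 <- binarize(exposed, genes, hotspot_only)
  b2 <- binarize(control, genes, hotspot_only)
  n1 <- ncol(b1)
  n2 <- ncol(b2)
  res <- tibble::tibble(
    gene = genes$genes,
    k1 = as.integer(rowSums(b1)),
    n1 = n1,
    k2 = as.integer(rowSums(b2)),
    n2 = n2
  ) |>
    dplyr::mutate(
      freq1 = .data$k1 / .data$n1,
      sd1 = beta_sd(.data$k1, .data$n1),
      freq2 = .data$k2 / .data$n2,
      sd2 = beta_sd(.data$k2, .data$n2),
      m = .data$k1 + .data$k2,
      min_p = purrr::pmap_dbl(
        list(.data$n1, .data$n2, .data$m),
        function(n1, n2, m) min_achievable_p(n1, n2, m, sidedness)
      ),
      corrected_min_p = pmin(1, .data$min_p * n_tests),
      powered = .data$corrected_min_p < alpha,
      p_value = purrr::pmap_dbl(
        list(.data$k1, .data$n1, .data$k2, .data$n2, .data$powered),
        function(k1, n1, k2, n2, powered) {
          if (!powered) return(NA_real_)
          fisher_2x2(
            matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE), sidedness
          )$p_value
        }
      ),
      q_value = {
        q <- rep(NA_real_, dplyr::n())
        idx <- which(.data$powered)
        if (length(idx) > 0) q[idx] <- bh_adjust(.data$p_value[idx])
        q
      }
    ) |>
    dplyr::arrange(.data$q_value, .data$corrected_min_p)
  attr(res, "sidedness") <- sidedness
  attr(res, "n_tests") <- n_tests
  attr(res, "alpha") <- alpha
  attr(res, "hotspot_only") <- hotspot_only
  class(res) <- c("freq_comparison", class(res))
  res
}

#' @export
tidy.freq_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.freq_comparison <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_powered = sum(x$powered),
    n_significant_q10 = sum(!is.na(x$q_value) & x$q_value < 0.1),
    sidedness = attr(x, "sidedness"),
    n_tests = attr(x, "n_tests"),
    alpha = attr(x, "alpha")
  )
}

#' Bar plot of a power-gated frequency comparison
#'
#' Paired per-gene frequency bars with beta-distribution error bars; powered
#' genes are labeled with their BH q-values.
#'
#' @param object A `freq_comparison` from [compare_gene_frequencies()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.freq_comparison <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      cols = c("freq1", "freq2"),
      names_to = "cohort", values_to = "freq"
    ) |>
    dplyr::mutate(
      cohort = ifelse(.data$cohort == "freq1", "exposed", "control"),
      sd = ifelse(.data$cohort == "exposed", .data$sd1, .data$sd2),
      label = ifelse(
        .data$cohort == "exposed" & !is.na(.data$q_value),
        sprintf("Q = %.2g", .data$q_value), ""
      )
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = stats::reorder(.data$gene, .data$freq2),
      y = .data$freq, fill = .data$cohort
    )
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$freq - .data$sd),
                   ymax = pmin(1, .data$freq + .data$sd)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$label, y = pmin(1, .data$freq + .data$sd) + 0.03),
      size = 3, hjust = 0
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mutation frequency", fill = "Cohort") +
    ggplot2::theme_minimal()
}
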