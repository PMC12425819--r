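# Clonality and timing: the cancer-cell-fraction clonality rule, simplified
# multiplicity-based timing relative to whole-genome duplication, early
# clonal driver counting, and the two-cohort comparison of early-event
# counts.

#' Clonal / subclonal classification by cancer cell fraction
#'
#' A mutation is clonal when its estimated cancer cell fraction reaches the
#' threshold (default 0.95, boundary inclusive) and subclonal otherwise.
#'
#' @param ccf Numeric vector of cancer cell fractions in \[0, 1\]; `NA`
#'   values propagate.
#' @param threshold Clonality threshold (default 0.95).
#' @return Character vector of `"clonal"` / `"subclonal"`.
#' @examples
#' classify_clonal(c(1, 0.95, 0.949))
#' @export
classify_clonal <- function(ccf, threshold = 0.95) {
  ok <- is.na(ccf) | (ccf >= 0 & ccf <= 1)
  if (!all(ok)) abort("classify_clonal: ccf must be in [0, 1]")
  ifelse(is.na(ccf), NA_character_,
    ifelse(ccf >= threshold, "clonal", "subclonal")
  )
}

#' Mutation timing relative to whole-genome duplication
#'
#' In a genome-doubled tumor, a clonal mutation present on both copies
#' (multiplicity >= 2) must have arisen before the doubling; multiplicity 1
#' places it after. Samples without WGD (or mutations without a multiplicity
#' estimate) are `not_applicable`.
#'
#' @param mutations Tibble of mutation records with a `multiplicity` column.
#' @param annotations Sample annotations with a `wgd` column.
#' @return The `mutations` tibble with an added `timing` column in
#'   `{"pre_WGD", "post_WGD", "not_applicable"}`.
#' @export
timing_vs_wgd <- function(mutations, annotations) {
  check_required_cols(annotations, c("sample_id", "wgd"), "annotations")
  joined <- dplyr::left_join(
    mutations,
    dplyr::select(annotations, "sample_id", "wgd"),
    by = "sample_id"
  )
  missing_mult <- isTRUE(any(joined$wgd & is.na(joined$multiplicity)))
  if (missing_mult) {
    warn("timing_vs_wgd: WGD sample(s) with missing multiplicity -> not_applicable")
  }
  mutations$timing <- dplyr::case_when(
    is.na(joined$wgd) | !joined$wgd ~ "not_applicable",
    is.na(joined$multiplicity) ~ "not_applicable",
    joined$multiplicity >= 2 ~ "pre_WGD",
    TRUE ~ "post_WGD"
  )
  mutations
}

#' Count early clonal driver genes in one sample
#'
#' The number of distinct driver genes in which the sample carries at least
#' one clonal nonsynonymous mutation (gene-level counting: several clonal
#' mutations in one gene are one event). Mutations without a CCF estimate are
#' excluded with a message.
#'
#' @param mutations The sample's mutation records.
#' @param driver_genes A [gene_list()] of early driver genes.
#' @param threshold CCF clonality threshold (default 0.95).
#' @param per_mutation Count clonal driver mutations instead of genes.
#' @return A nonnegative integer.
#' @export
count_early_clonal_drivers <- function(mutations, driver_genes,
                                       threshold = 0.95,
                                       per_mutation = FALSE) {
  mut <- filter_nonsynonymous(mutations) |>
    dplyr::filter(.data$gene %in% driver_genes$genes)
  n_na <- sum(is.na(mut$ccf))
  if (n_na > 0) {
    inform(sprintf(
      "count_early_clonal_drivers: excluded %d driver mutation(s) without CCF", n_na
    ))
  }
  clonal <- dplyr::filter(
    mut, !is.na(.data$ccf),
    classify_clonal(.data$ccf, threshold) == "clonal"
  )
  if (per_mutation) nrow(clonal) else dplyr::n_distinct(clonal$gene)
}

per_sample_early_counts <- function(cohort, driver_genes, threshold) {
  counts <- purrr::map_int(cohort$annotations$sample_id, function(sid) {
    as.integer(suppressMessages(count_early_clonal_drivers(
      dplyr::filter(cohort$mutations, .data$sample_id == sid),
      driver_genes, threshold
    )))
  })
  tibble::tibble(sample_id = cohort$annotations$sample_id, n_early = counts)
}

#' Compare early clonal driver-event counts between cohorts
#'
#' Counts early clonal driver genes per sample in both cohorts, compares the
#' distributions with the two-sided rank-sum test, and additionally tests
#' whether the deficit in the exposed cohort is larger than a stated number
#' of events by re-running the comparison with the exposed counts shifted up
#' ([shift_compare()]). Also returns the per-count density histogram with
#' beta-distribution SDs for plotting.
#'
#' @param exposed,control [cohort()] objects with CCFs on their mutations.
#' @param driver_genes A [gene_list()] of early driver genes.
#' @param shift Event shift for the secondary test (default 1).
#' @param threshold CCF clonality threshold.
#' @return A list of class `early_count_comparison`: `counts` (per-sample
#'   tibble), `medians`, `test` (rank-sum `mut_test`), `shift_test`, and
#'   `histogram` (cohort, n_early, k, n, fraction, sd).
#' @export
compare_early_counts <- function(exposed, control, driver_genes,
                                 shift = 1L, threshold = 0.95) {
  stopifnot(inherits(exposed, "cohort"), inherits(control, "cohort"))
  if (nrow(exposed$annotations) == 0 || nrow(control$annotations) == 0) {
    abort("compare_early_counts: empty cohort")
  }
  ce <- per_sample_early_counts(exposed, driver_genes, threshold)
  cc <- per_sample_early_counts(control, driver_genes, threshold)
  counts <- dplyr::bind_rows(
    dplyr::mutate(ce, cohort = "exposed"),
    dplyr::mutate(cc, cohort = "control")
  )
  hist <- counts |>
    dplyr::count(.data$cohort, .data$n_early, name = "k") |>
    dplyr::group_by(.data$cohort) |>
    dplyr::mutate(
      n = sum(.data$k),
      fraction = .data$k / .data$n,
      sd = beta_sd(.data$k, .data$n)
    ) |>
    dplyr::ungroup()
  structure(
    list(
      counts = counts,
      medians = c(exposed = median(ce$n_early), control = median(cc$n_early)),
      test = rank_sum(ce$n_early, cc$n_early, "two_sided"),
      shift_test = shift_compare(ce$n_early, cc$n_early, shift, "two_sided"),
      histogram = hist
    ),
    class = "early_count_comparison"
  )
}

#' @export
print.early_count_comparison <- function(x, ...) {
  cat(sprintf(
    "<early_count_comparison> medians %g (exposed) vs %g (control); P = %.3g; shifted (+%d) P = %.3g\n",
    x$medians["exposed"], x$medians["control"],
    x$test$p_value, x$shift_test$shift, x$shift_test$p_value
  ))
  invisible(x)
}

#' @export
tidy.early_count_comparison <- function(x, ...) x$histogram

#' @export
glance.early_count_comparison <- function(x, ...) {
  tibble::tibble(
    median_exposed = unname(x$medians["exposed"]),
    median_control = unname(x$medians["control"]),
    p_value = x$test$p_value,
    shift = x$shift_test$shift,
    shift_p_value = x$shift_test$p_value
  )
}

#' Density histogram of early-event counts per cohort
#'
#' @param object An `early_count_comparison` from [compare_early_counts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.early_count_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$histogram,
    ggplot2::aes(
      x = factor(.data$n_early), y = .data$fraction, fill = .data$cohort
    )
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$fraction - .data$sd),
                   ymax = pmin(1, .data$fraction + .data$sd)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3
    ) +
    ggplot2::labs(
      x = "Early clonal driver events per sample",
      y = "Fraction of tumors", fill = "Cohort"
    ) +
    ggplot2::theme_minimal()
}
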