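# Scalar summaries: mutational burden, SCNA genome fraction, droplet digital
# PCR allele-fraction calling, and the expected number of background
# (exposure-unrelated) cases among exposed patients.

#' Mutational burden in mutations per megabase
#'
#' @param n_mutations Number of called somatic mutations (vectorized). By
#'   convention the burden numerator is all called coding mutations,
#'   including silent ones (the nonsynonymous filter is applied later, for
#'   driver comparisons only).
#' @param territory_mb Sequenced coding territory in Mb (default 37).
#' @return Mutations per Mb.
#' @examples
#' mutation_burden(74, 37) # 2
#' @export
mutation_burden <- function(n_mutations, territory_mb = 37) {
  if (any(territory_mb <= 0)) abort("mutation_burden: territory must be positive")
  n_mutations / territory_mb
}

#' Per-sample mutational burden for a cohort
#'
#' @param cohort A [cohort()].
#' @return Tibble with `sample_id`, `n_mutations`, `burden`.
#' @export
mutation_burden_by_sample <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  cohort$annotations |>
    dplyr::select("sample_id") |>
    dplyr::left_join(
      dplyr::count(cohort$mutations, .data$sample_id, name = "n_mutations"),
      by = "sample_id"
    ) |>
    dplyr::mutate(
      n_mutations = dplyr::coalesce(.data$n_mutations, 0L),
      burden = mutation_burden(.data$n_mutations, cohort$territory_mb)
    )
}

#' Fraction of the genome affected by copy-number alteration
#'
#' The fraction of the covered territory carried by segments whose absolute
#' copy-number change reaches the amplitude threshold (gains and deletions
#' both count, unlike the deletions-only rule of
#' [deleted_genome_fraction()]).
#'
#' @param segments Copy-number segments of one sample.
#' @param amplitude_threshold Minimal `|seg_value|` to count as altered.
#' @param territory_mb Optional explicit denominator in Mb; defaults to the
#'   total covered segment length.
#' @return A fraction in \[0, 1\].
#' @export
scna_fraction <- function(segments, amplitude_threshold, territory_mb = NULL) {
  lengths <- segments$end - segments$start + 1
  total <- if (is.null(territory_mb)) sum(lengths) else territory_mb * 1e6
  if (!isTRUE(total > 0)) abort("scna_fraction: zero covered territory")
  sum(lengths[abs(segments$seg_value) >= amplitude_threshold]) / total
}

#' Droplet digital PCR allele fraction
#'
#' `AF = mutant / (mutant + wildtype) * 100`, in percent.
#'
#' @param n_mutant,n_wildtype Droplet counts (vectorized); each well must
#'   have at least one droplet.
#' @return Allele fraction(s) in percent, in \[0, 100\].
#' @export
ddpcr_af <- function(n_mutant, n_wildtype) {
  if (any(n_mutant < 0) || any(n_wildtype < 0)) {
    abort("ddpcr_af: droplet counts must be nonnegative")
  }
  total <- n_mutant + n_wildtype
  if (any(total == 0)) abort("ddpcr_af: zero total droplets")
  n_mutant / total * 100
}

#' ddPCR calling parameters
#'
#' @param af_cutoff_percent Allele-fraction cutoff in percent; a well is
#'   positive only strictly above it (default 2, chosen to suppress
#'   FFPE-associated artifacts).
#' @param hotspot_panel Named list mapping gene to hotspot protein changes
#'   (default the PIK3CA E542K/E545K/H1047R panel).
#' @return A list of class `ddpcr_params`.
#' @export
ddpcr_params <- function(af_cutoff_percent = 2,
                         hotspot_panel = list(
                           PIK3CA = c("p.E542K", "p.E545K", "p.H1047R")
                         )) {
  if (af_cutoff_percent <= 0 || af_cutoff_percent >= 100) {
    abort("af_cutoff_percent must be in (0, 100)")
  }
  structure(
    list(af_cutoff_percent = af_cutoff_percent, hotspot_panel = hotspot_panel),
    class = "ddpcr_params"
  )
}

#' Call a ddPCR well positive or negative
#'
#' Positive iff the allele fraction strictly exceeds the cutoff: a well at
#' exactly the cutoff is negative.
#'
#' @param n_mutant,n_wildtype Droplet counts (vectorized).
#' @param params A [ddpcr_params()].
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
call_ddpcr <- function(n_mutant, n_wildtype, params = ddpcr_params()) {
  af <- ddpcr_af(n_mutant, n_wildtype)
  ifelse(af > params$af_cutoff_percent, "positive", "negative")
}

#' Call a table of ddPCR wells
#'
#' @param wells Tibble with columns `sample_id`, `assay`, `mutant_droplets`,
#'   `wildtype_droplets`.
#' @param params A [ddpcr_params()].
#' @return The input with added `af` (percent) and `call` columns.
#' @export
call_ddpcr_wells <- function(wells, params = ddpcr_params()) {
  check_required_cols(
    wells, c("sample_id", "assay", "mutant_droplets", "wildtype_droplets"),
    "ddPCR wells table"
  )
  dplyr::mutate(
    tibble::as_tibble(wells),
    af = ddpcr_af(.data$mutant_droplets, .data$wildtype_droplets),
    call = call_ddpcr(.data$mutant_droplets, .data$wildtype_droplets, params)
  )
}

#' Expected number of exposure-unrelated cases among exposed patients
#'
#' If exposure multiplies the absolute cancer risk from `baseline_risk` to
#' `treated_risk`, then among `n` exposed cases a fraction
#' `baseline_risk / treated_risk` is expected to have arisen independently of
#' the exposure. With the default risks (0.5% untreated vs ~2.5% under
#' treatment, a fivefold increase) 21 cases give 4.2, presented as
#' "approximately 4".
#'
#' @param n_exposed_cases Number of cancer cases in the exposed cohort.
#' @param baseline_risk Absolute risk without exposure (default 0.005).
#' @param treated_risk Absolute risk under exposure (default 0.025).
#' @return One-row tibble with `n`, `baseline_risk`, `treated_risk`,
#'   `expected` and the nearest-integer `presented` value.
#' @examples
#' expected_background_cases(21)
#' @export
expected_background_cases <- function(n_exposed_cases,
                                      baseline_risk = 0.005,
                                      treated_risk = 0.025) {
  if (treated_risk <= 0) abort("treated_risk must be positive")
  if (baseline_risk <= 0 || baseline_risk > treated_risk) {
    abort("need 0 < baseline_risk <= treated_risk")
  }
  expected <- n_exposed_cases * baseline_risk / treated_risk
  tibble::tibble(
    n = n_exposed_cases,
    baseline_risk = baseline_risk,
    treated_risk = treated_risk,
    expected = expected,
    presented = round(expected)
  )
}
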