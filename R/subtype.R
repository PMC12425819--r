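# Molecular subtyping: SBS96 mutation spectra, NNLS signature attribution,
# the purity-normalized deleted-genome-fraction rule, and the
# POLE -> MSI -> CIN/GS classification cascade.

SUBSTITUTION_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The 96 single-base-substitution channel labels
#'
#' Pyrimidine-strand substitution-in-trinucleotide-context labels in the
#' conventional order: substitution type (C>A, C>G, C>T, T>A, T>C, T>G)
#' varying slowest, then the 5' base, then the 3' base, e.g. `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SUBSTITUTION_TYPES, function(sub) {
    unlist(lapply(BASES, function(five) {
      paste0(five, "[", sub, "]", BASES)
    }))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(
    strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), character(1)
  ))
}

#' Tally mutations into the 96 substitution channels
#'
#' Collapses single-nucleotide variants onto the pyrimidine strand (records
#' whose reference allele is A or G are reverse-complemented together with
#' their trinucleotide context) and counts them per channel. Non-SNV records
#' and records without a context are skipped with a message. A context whose
#' middle base disagrees with the reference allele is an error.
#'
#' @param mutations Tibble of mutation records with `ref_allele`,
#'   `alt_allele` and `trinucleotide_context`.
#' @return Named integer vector over [sbs96_channels()]; the total equals the
#'   number of usable SNVs.
#' @export
sbs96_vector <- function(mutations) {
  channels <- sbs96_channels()
  out <- setNames(integer(96), channels)
  if (nrow(mutations) == 0) return(out)
  is_snv <- nchar(mutations$ref_allele) == 1 &
    nchar(mutations$alt_allele) == 1 &
    mutations$ref_allele %in% BASES &
    mutations$alt_allele %in% BASES &
    !is.na(mutations$trinucleotide_context) &
    nchar(mutations$trinucleotide_context) == 3
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    inform(sprintf("sbs96_vector: skipped %d non-SNV or context-less record(s)", n_skipped))
  }
  snv <- mutations[is_snv, ]
  if (nrow(snv) == 0) return(out)
  ref <- snv$ref_allele
  alt <- snv$alt_allele
  ctx <- toupper(snv$trinucleotide_context)
  flip <- ref %in% c("A", "G")
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  mid <- substr(ctx, 2, 2)
  bad <- mid != ref
  if (any(bad)) {
    abort(sprintf(
      "sbs96_vector: trinucleotide context inconsistent with ref allele at row(s) %s",
      paste(head(which(is_snv)[bad], 5), collapse = ", ")
    ))
  }
  label <- paste0(
    substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3)
  )
  tab <- table(factor(label, levels = channels))
  out[] <- as.integer(tab)
  out
}

#' Read a 96-channel signature catalog
#'
#' Expects a tab-separated table whose first column holds the channel labels
#' (any order; matched against [sbs96_channels()]) and each further column a
#' signature profile summing to 1.
#'
#' @param path Path to the catalog TSV.
#' @return Numeric matrix, 96 rows (canonical channel order) by one column
#'   per signature.
#' @export
read_signature_catalog <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    channel = readr::col_character()
  ))
  check_required_cols(df, "channel", sprintf("catalog '%s'", path))
  validate_catalog(
    as.matrix(df[match(sbs96_channels(), df$channel), -1, drop = FALSE])
  )
}

validate_catalog <- function(catalog) {
  catalog <- as.matrix(catalog)
  if (nrow(catalog) != 96) abort("signature catalog must have 96 rows")
  if (any(is.na(catalog)) || any(catalog < 0)) {
    abort("signature catalog entries must be nonnegative")
  }
  if (any(abs(colSums(catalog) - 1) > 1e-9)) {
    abort("signature catalog columns must each sum to 1")
  }
  rownames(catalog) <- sbs96_channels()
  catalog
}

#' Attribute a mutation spectrum to catalog signatures by NNLS
#'
#' Projects an observed 96-channel count vector onto the nonnegative cone of
#' a fixed signature catalog: exposures are the nonnegative least-squares
#' solution minimizing the squared reconstruction error. Deterministic;
#' exposures are on the mutation-count scale and fractions are exposures
#' divided by the total count.
#'
#' @param counts96 Integer vector of length 96 (channel order of
#'   [sbs96_channels()]).
#' @param catalog 96 x k signature matrix (columns sum to 1).
#' @return Tibble with `signature`, `exposure` and `fraction`; the squared
#'   residual norm is attached as attribute `residual`.
#' @export
nnls_exposures <- function(counts96, catalog) {
  catalog <- validate_catalog(catalog)
  if (length(counts96) != 96) abort("counts96 must have length 96")
  sigs <- colnames(catalog) %||% paste0("S", seq_len(ncol(catalog)))
  total <- sum(counts96)
  if (total == 0) {
    warn("nnls_exposures: zero total counts; returning zero exposures")
    out <- tibble::tibble(signature = sigs, exposure = 0, fraction = 0)
    attr(out, "residual") <- 0
    return(out)
  }
  fit <- pracma::lsqnonneg(catalog, as.numeric(counts96))
  out <- tibble::tibble(
    signature = sigs,
    exposure = fit$x,
    fraction = fit$x / total
  )
  attr(out, "residual") <- fit$resid.norm
  out
}

#' Parameters of the molecular-subtype cascade
#'
#' @param r1 Deletion amplitude threshold on the copy-ratio-change scale
#'   (default 0.36); a segment counts as deleted when its `seg_value` is at
#'   or below `-r1 * purity`.
#' @param r2 Deleted-genome-fraction threshold separating CIN from GS
#'   (default 0.034; CIN when the fraction is strictly larger).
#' @param pole_signatures,msi_signatures Signature names whose summed
#'   exposure fraction constitutes evidence for the POLE and MSI subtypes.
#' @param pole_domain Protein-position range of the POLE exonuclease domain
#'   (default 268-471).
#' @param signature_fraction_threshold Minimal summed exposure fraction that
#'   counts as signature evidence (default 0.2).
#' @param purity_normalization `"multiply"` (default; effective threshold
#'   `r1 * purity`, since lower purity shrinks the apparent copy-number
#'   change of a clonal deletion) or `"divide"`.
#' @return A list of class `subtype_params`.
#' @export
subtype_params <- function(r1 = 0.36,
                           r2 = 0.034,
                           pole_signatures = c("SBS10a", "SBS10b", "SBS14"),
                           msi_signatures = c("SBS6", "SBS14", "SBS15", "SBS20",
                                              "SBS21", "SBS26", "SBS44"),
                           pole_domain = c(268L, 471L),
                           signature_fraction_threshold = 0.2,
                           purity_normalization = c("multiply", "divide")) {
  if (r1 <= 0 || r2 <= 0) abort("r1 and r2 must be positive")
  if (signature_fraction_threshold <= 0 || signature_fraction_threshold >= 1) {
    abort("signature_fraction_threshold must be in (0, 1)")
  }
  structure(
    list(
      r1 = r1, r2 = r2,
      pole_signatures = pole_signatures,
      msi_signatures = msi_signatures,
      pole_domain = pole_domain,
      signature_fraction_threshold = signature_fraction_threshold,
      purity_normalization = match.arg(purity_normalization)
    ),
    class = "subtype_params"
  )
}

signature_fraction <- function(exposures, signatures) {
  sum(exposures$fraction[exposures$signature %in% signatures])
}

#' POLE-subtype evidence for one sample
#'
#' A sample is POLE when it carries at least one nonsynonymous POLE mutation
#' inside the exonuclease domain *and* the summed fraction of POLE-associated
#' signatures reaches the evidence threshold.
#'
#' @param mutations The sample's mutation records.
#' @param exposures Signature exposures from [nnls_exposures()].
#' @param params A [subtype_params()].
#' @return `TRUE` or `FALSE`.
#' @export
classify_pole <- function(mutations, exposures, params = subtype_params()) {
  pole_mut <- filter_nonsynonymous(mutations) |>
    dplyr::filter(
      .data$gene == "POLE",
      !is.na(.data$protein_position),
      .data$protein_position >= params$pole_domain[1],
      .data$protein_position <= params$pole_domain[2]
    )
  nrow(pole_mut) > 0 &&
    signature_fraction(exposures, params$pole_signatures) >=
      params$signature_fraction_threshold
}

#' MSI-subtype evidence for one sample
#'
#' If the annotation carries an `msi_flag` (an upstream microsatellite
#' instability call) it takes precedence; otherwise the summed fraction of
#' MSI-associated signatures is compared against the evidence threshold.
#'
#' @param annotation A one-row annotation tibble (or a list with `msi_flag`).
#' @param exposures Signature exposures from [nnls_exposures()].
#' @param params A [subtype_params()].
#' @return `TRUE` or `FALSE`.
#' @export
classify_msi <- function(annotation, exposures, params = subtype_params()) {
  flag <- annotation$msi_flag
  if (length(flag) == 1 && !is.na(flag)) return(isTRUE(as.logical(flag)))
  signature_fraction(exposures, params$msi_signatures) >=
    params$signature_fraction_threshold
}

#' Purity-normalized deleted genome fraction
#'
#' The fraction of the covered genome carried by segments whose copy-number
#' change is at or below the deletion threshold. Because a clonal deletion's
#' apparent change shrinks in impure samples, the amplitude threshold `r1` is
#' normalized by the sample purity (multiplied by default).
#'
#' @param segments The sample's copy-number segments.
#' @param purity Sample purity in (0, 1].
#' @param params A [subtype_params()].
#' @param territory_mb Optional explicit denominator in Mb; by default the
#'   total length of the supplied segments (the covered territory).
#' @return A fraction in \[0, 1\].
#' @export
deleted_genome_fraction <- function(segments, purity,
                                    params = subtype_params(),
                                    territory_mb = NULL) {
  if (is.na(purity) || purity <= 0 || purity > 1) {
    abort("deleted_genome_fraction: purity must be in (0, 1]")
  }
  lengths <- segments$end - segments$start + 1
  total <- if (is.null(territory_mb)) sum(lengths) else territory_mb * 1e6
  if (!isTRUE(total > 0)) abort("deleted_genome_fraction: zero covered territory")
  thr <- switch(params$purity_normalization,
    multiply = params$r1 * purity,
    divide = params$r1 / purity
  )
  deleted <- sum(lengths[segments$seg_value <= -thr])
  deleted / total
}

#' Classify every sample of a cohort into molecular subtypes
#'
#' The TCGA-style cascade: a sample is POLE if it has an exonuclease-domain
#' POLE mutation with supporting signatures; otherwise MSI if flagged or
#' supported by MSI signatures; the rest are CIN when their purity-normalized
#' deleted genome fraction exceeds `r2`, and genomically stable (GS)
#' otherwise. Each sample receives exactly one subtype, with the evidence
#' recorded.
#'
#' @param cohort A [cohort()].
#' @param catalog 96 x k signature catalog matrix.
#' @param params A [subtype_params()].
#' @return A tibble of class `subtype_calls`: `sample_id`, `subtype`,
#'   `pole_flag`, `pole_fraction`, `msi_source`, `msi_fraction`,
#'   `deleted_fraction`.
#' @export
classify_subtype <- function(cohort, catalog, params = subtype_params()) {
  stopifnot(inherits(cohort, "cohort"))
  catalog <- validate_catalog(catalog)
  rows <- purrr::map(cohort$annotations$sample_id, function(sid) {
    ann <- dplyr::filter(cohort$annotations, .data$sample_id == sid)
    mut <- dplyr::filter(cohort$mutations, .data$sample_id == sid)
    seg <- dplyr::filter(cohort$segments, .data$sample_id == sid)
    exposures <- suppressMessages(nnls_exposures(sbs96_vector(mut), catalog))
    pole_fraction <- signature_fraction(exposures, params$pole_signatures)
    msi_fraction <- signature_fraction(exposures, params$msi_signatures)
    pole <- classify_pole(mut, exposures, params)
    msi <- classify_msi(ann, exposures, params)
    msi_source <- if (!is.na(ann$msi_flag)) "flag" else "signatures"
    deleted <- if (nrow(seg) > 0) {
      deleted_genome_fraction(seg, ann$purity, params)
    } else {
      0
    }
    subtype <- if (pole) {
      "POLE"
    } else if (msi) {
      "MSI"
    } else if (deleted > params$r2) {
      "CIN"
    } else {
      "GS"
    }
    tibble::tibble(
      sample_id = sid, subtype = subtype,
      pole_flag = pole, pole_fraction = pole_fraction,
      msi_source = msi_source, msi_fraction = msi_fraction,
      deleted_fraction = deleted
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("subtype_calls", class(out))
  out
}

#' Stacked subtype-composition plot
#'
#' @param object A `subtype_calls` tibble from [classify_subtype()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subtype_calls <- function(object, ...) {
  counts <- tibble::as_tibble(object) |>
    dplyr::count(.data$subtype) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  ggplot2::ggplot(
    counts,
    ggplot2::aes(x = "", y = .data$fraction, fill = .data$subtype)
  ) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(x = NULL, y = "Fraction of samples", fill = "Subtype") +
    ggplot2::theme_minimal()
}
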