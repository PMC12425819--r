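# Tabular I/O and the core data model: mutation records, copy-number
# segments, sample annotations, cohorts and gene lists. All coordinates are
# 1-based with inclusive ends (the MAF/SEG community convention).

#' Controlled vocabulary of variant classifications
#'
#' The MAF-style variant classification labels accepted by [read_maf()] and
#' the rest of the package. Classifications outside this set are rejected at
#' read time so that the nonsynonymous filter is well defined.
#'
#' @return Character vector of accepted classification labels.
#' @export
variant_classes <- function() {
  c(
    "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
    "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del", "Splice_Site",
    "Nonstop_Mutation", "Translation_Start_Site", "Silent",
    "3'UTR", "5'UTR", "IGR", "Intron", "lincRNA", "RNA"
  )
}

# classifications removed by the nonsynonymous filter
noncoding_classes <- function() {
  c("3'UTR", "5'UTR", "IGR", "Intron", "lincRNA", "RNA", "Silent")
}

maf_required_cols <- c(
  "sample_id", "gene", "chromosome", "start",
  "ref_allele", "alt_allele", "variant_classification"
)

maf_optional_cols <- c(
  "protein_change", "protein_position", "trinucleotide_context",
  "ccf", "multiplicity"
)

check_required_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

validate_mutations <- function(mut, what = "mutation table") {
  check_required_cols(mut, maf_required_cols, what)
  bad_class <- setdiff(unique(mut$variant_classification), variant_classes())
  if (length(bad_class) > 0) {
    abort(sprintf(
      "%s contains variant_classification value(s) outside the controlled set: %s",
      what, paste(bad_class, collapse = ", ")
    ))
  }
  if (any(is.na(mut$start)) || any(mut$start < 1)) {
    bad <- which(is.na(mut$start) | mut$start < 1)
    abort(sprintf(
      "%s has unparseable or non-positive start position(s) at row(s): %s",
      what, paste(head(bad, 5), collapse = ", ")
    ))
  }
  if (any(mut$ref_allele == mut$alt_allele)) {
    abort(sprintf("%s has row(s) with ref_allele == alt_allele", what))
  }
  if ("ccf" %in% names(mut)) {
    ccf <- mut$ccf[!is.na(mut$ccf)]
    if (any(ccf < 0 | ccf > 1)) {
      abort(sprintf("%s has ccf value(s) outside [0, 1]", what))
    }
  }
  invisible(mut)
}

#' Read a MAF-style somatic mutation table
#'
#' Reads a tab-separated mutation table with one row per somatic variant.
#' Required columns: `sample_id`, `gene`, `chromosome`, `start`,
#' `ref_allele`, `alt_allele`, `variant_classification`. Optional columns
#' (`protein_change`, `protein_position`, `trinucleotide_context`, `ccf`,
#' `multiplicity`) are typed when present and left as `NA` columns when
#' absent. Coordinates are 1-based. Duplicate records (same sample, gene,
#' position and alternate allele) are collapsed to one with a warning.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble of mutation records.
#' @seealso [write_maf()], [filter_nonsynonymous()]
#' @export
read_maf <- function(path) {
  mut <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  check_required_cols(mut, maf_required_cols, sprintf("MAF file '%s'", path))
  start_num <- suppressWarnings(as.numeric(mut$start))
  bad <- which(!is.na(mut$start) & is.na(start_num))
  if (length(bad) > 0) {
    abort(sprintf(
      "MAF file '%s': unparseable start position at line(s) %s",
      path, paste(bad + 1L, collapse = ", ")
    ))
  }
  mut$start <- as.integer(start_num)
  for (col in maf_optional_cols) {
    if (!col %in% names(mut)) mut[[col]] <- NA
  }
  mut <- dplyr::mutate(
    mut,
    protein_change = as.character(.data$protein_change),
    protein_position = as.integer(.data$protein_position),
    trinucleotide_context = as.character(.data$trinucleotide_context),
    ccf = as.numeric(.data$ccf),
    multiplicity = as.integer(.data$multiplicity)
  )
  validate_mutations(mut, sprintf("MAF file '%s'", path))
  dup <- duplicated(mut[, c("sample_id", "gene", "start", "alt_allele")])
  if (any(dup)) {
    warn(sprintf(
      "MAF file '%s': collapsed %d duplicate record(s) (same sample/gene/position/alt)",
      path, sum(dup)
    ))
    mut <- mut[!dup, ]
  }
  tibble::as_tibble(mut)
}

#' Write a MAF-style mutation table
#'
#' @param mutations Tibble of mutation records as produced by [read_maf()].
#' @param path Output path; tab-separated, UTF-8, Unix newlines, header row.
#' @return `path`, invisibly.
#' @export
write_maf <- function(mutations, path) {
  validate_mutations(mutations)
  readr::write_tsv(mutations, path)
  invisible(path)
}

#' Read a SEG-style copy-number segment table
#'
#' Reads tab-separated copy-number segments with columns `sample_id`,
#' `chromosome`, `start`, `end`, `seg_value` and optionally `n_probes`.
#' `seg_value` is the signed copy-number change of the segment relative to
#' the sample baseline, on the linear copy-ratio scale (deletions negative).
#' Coordinates are 1-based inclusive; segment length is `end - start + 1`.
#' Segments are sorted within sample and chromosome, and overlaps within a
#' sample/chromosome are rejected.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble of segments.
#' @export
read_seg <- function(path) {
  seg <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    chromosome = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double(),
    .default = readr::col_double()
  ))
  check_required_cols(
    seg, c("sample_id", "chromosome", "start", "end", "seg_value"),
    sprintf("SEG file '%s'", path)
  )
  if (!"n_probes" %in% names(seg)) seg$n_probes <- NA_integer_
  validate_segments(seg, sprintf("SEG file '%s'", path))
  seg <- dplyr::arrange(seg, .data$sample_id, .data$chromosome, .data$start)
  tibble::as_tibble(seg)
}

validate_segments <- function(seg, what = "segment table") {
  bad <- which(seg$start > seg$end)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: start > end at row(s) %s", what, paste(head(bad, 5), collapse = ", ")
    ))
  }
  overlaps <- seg |>
    dplyr::group_by(.data$sample_id, .data$chromosome) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() > 1 &
      .data$start <= dplyr::lag(.data$end)) |>
    dplyr::ungroup()
  if (nrow(overlaps) > 0) {
    abort(sprintf(
      "%s: overlapping segments within a sample/chromosome: %s",
      what,
      paste(sprintf(
        "%s:%s:%d", overlaps$sample_id, overlaps$chromosome,
        as.integer(overlaps$start)
      ), collapse = "; ")
    ))
  }
  invisible(seg)
}

#' Write a SEG-style segment table
#'
#' @param segments Tibble of segments as produced by [read_seg()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  validate_segments(segments)
  readr::write_tsv(segments, path)
  invisible(path)
}

parse_flexible_logical <- function(x, what) {
  if (is.logical(x)) return(x)
  lower <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lower %in% c("true", "1", "yes")] <- TRUE
  out[lower %in% c("false", "0", "no")] <- FALSE
  bad <- !is.na(x) & is.na(out) & lower != "na" & lower != ""
  if (any(bad)) {
    abort(sprintf(
      "unparseable boolean value(s) in %s: %s",
      what, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  out
}

annotation_cols <- c(
  "sample_id", "cohort", "purity", "ploidy", "wgd", "histology",
  "grade", "tamoxifen_years", "msi_flag", "bmi"
)

validate_annotations <- function(ann, what = "annotation table") {
  check_required_cols(ann, c("sample_id", "cohort"), what)
  bad_cohort <- setdiff(unique(ann$cohort), c("exposed", "control"))
  if (length(bad_cohort) > 0) {
    abort(sprintf(
      "%s: unknown cohort label(s) %s (must be 'exposed' or 'control')",
      what, paste(bad_cohort, collapse = ", ")
    ))
  }
  if ("purity" %in% names(ann)) {
    p <- ann$purity[!is.na(ann$purity)]
    if (any(p <= 0 | p > 1)) {
      abort(sprintf("%s: purity value(s) outside (0, 1]", what))
    }
  }
  invisible(ann)
}

#' Read a per-sample annotation table
#'
#' Reads tab-separated sample annotations. `sample_id` and `cohort`
#' (either `"exposed"` or `"control"`) are mandatory; `purity` (in (0, 1]),
#' `ploidy`, `wgd`, `histology`, `grade`, `tamoxifen_years`, `msi_flag` and
#' `bmi` are optional. Boolean columns accept true/false, 0/1 and yes/no in
#' any case.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble of sample annotations.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  what <- sprintf("annotation file '%s'", path)
  check_required_cols(ann, c("sample_id", "cohort"), what)
  for (col in setdiff(annotation_cols, names(ann))) ann[[col]] <- NA
  ann <- dplyr::mutate(
    ann,
    purity = as.numeric(.data$purity),
    ploidy = as.numeric(.data$ploidy),
    wgd = parse_flexible_logical(.data$wgd, "wgd"),
    msi_flag = parse_flexible_logical(.data$msi_flag, "msi_flag"),
    histology = as.character(.data$histology),
    grade = as.character(.data$grade),
    tamoxifen_years = as.numeric(.data$tamoxifen_years),
    bmi = as.numeric(.data$bmi)
  )
  validate_annotations(ann, what)
  tibble::as_tibble(ann)
}

#' Write a per-sample annotation table
#'
#' @param annotations Tibble as produced by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' Remove noncoding and silent mutations
#'
#' Drops records classified as 3'UTR, 5'UTR, IGR, Intron, lincRNA, RNA or
#' Silent, keeping everything else (the nonsynonymous filter applied before
#' any driver-frequency comparison). Input order is preserved and the filter
#' is idempotent.
#'
#' @param mutations Tibble of mutation records.
#' @return The filtered tibble.
#' @export
filter_nonsynonymous <- function(mutations) {
  validate_mutations(mutations)
  out <- dplyr::filter(
    mutations,
    !.data$variant_classification %in% noncoding_classes()
  )
  attr(out, "nonsynonymous_filtered") <- TRUE
  out
}

#' Bundle mutations, segments and annotations into a cohort
#'
#' A cohort is the unit the comparison functions operate on: per-sample
#' annotations plus the sample's somatic mutations and copy-number segments,
#' together with the size of the sequenced coding territory in megabases
#' (default 37 Mb, a standard whole-exome target).
#'
#' @param annotations Tibble of sample annotations (see [read_annotations()]).
#' @param mutations Tibble of mutation records; every `sample_id` must appear
#'   in `annotations`. May be empty.
#' @param segments Tibble of copy-number segments; same sample constraint.
#' @param territory_mb Positive coding territory in Mb.
#' @return An object of class `cohort`.
#' @export
cohort <- function(annotations,
                   mutations = empty_mutations(),
                   segments = empty_segments(),
                   territory_mb = 37) {
  validate_annotations(annotations)
  validate_mutations(mutations)
  validate_segments(segments)
  if (!is.numeric(territory_mb) || length(territory_mb) != 1 || territory_mb <= 0) {
    abort("territory_mb must be a single positive number")
  }
  orphans <- setdiff(
    c(unique(mutations$sample_id), unique(segments$sample_id)),
    annotations$sample_id
  )
  if (length(orphans) > 0) {
    abort(sprintf(
      "mutation/segment sample_id(s) absent from annotations: %s",
      paste(head(orphans, 5), collapse = ", ")
    ))
  }
  structure(
    list(
      annotations = tibble::as_tibble(annotations),
      mutations = tibble::as_tibble(mutations),
      segments = tibble::as_tibble(segments),
      territory_mb = territory_mb
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d samples (%s), %d mutations, %d segments, %.0f Mb territory\n",
    nrow(x$annotations),
    paste(sprintf(
      "%s: %d", names(table(x$annotations$cohort)),
      as.integer(table(x$annotations$cohort))
    ), collapse = ", "),
    nrow(x$mutations), nrow(x$segments), x$territory_mb
  ))
  invisible(x)
}

#' Empty mutation / segment tables with the canonical columns
#'
#' @return A zero-row tibble with the standard typed columns.
#' @export
empty_mutations <- function() {
  tibble::tibble(
    sample_id = character(), gene = character(), chromosome = character(),
    start = integer(), ref_allele = character(), alt_allele = character(),
    variant_classification = character(), protein_change = character(),
    protein_position = integer(), trinucleotide_context = character(),
    ccf = numeric(), multiplicity = integer()
  )
}

#' @rdname empty_mutations
#' @export
empty_segments <- function() {
  tibble::tibble(
    sample_id = character(), chromosome = character(),
    start = numeric(), end = numeric(), seg_value = numeric(),
    n_probes = integer()
  )
}

#' Define a named gene panel, optionally with hotspot protein changes
#'
#' @param name Panel name.
#' @param genes Character vector of unique gene symbols (order kept).
#' @param hotspots Optional named list mapping a gene symbol to the protein
#'   changes (e.g. `"p.E545K"`) that count as hotspot mutations for it.
#' @return An object of class `gene_list`.
#' @export
gene_list <- function(name, genes, hotspots = NULL) {
  if (anyDuplicated(genes)) abort("gene_list: duplicate gene symbols")
  if (!is.null(hotspots)) {
    stray <- setdiff(names(hotspots), genes)
    if (length(stray) > 0) {
      abort(sprintf(
        "gene_list: hotspot set(s) for gene(s) not in the panel: %s",
        paste(stray, collapse = ", ")
      ))
    }
  }
  structure(
    list(name = name, genes = as.character(genes), hotspots = hotspots),
    class = "gene_list"
  )
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf(
    "<gene_list> '%s': %d genes%s\n", x$name, length(x$genes),
    if (is.null(x$hotspots)) "" else sprintf(" (%d with hotspots)", length(x$hotspots))
  ))
  invisible(x)
}

#' Gene-by-sample mutation indicator matrix
#'
#' Builds the logical matrix underlying every frequency comparison: entry
#' `[gene, sample]` is `TRUE` iff the sample carries at least one qualifying
#' nonsynonymous mutation in the gene. With `hotspot_only = TRUE` only
#' records whose `protein_change` is in the gene's hotspot set qualify.
#' The nonsynonymous filter is applied internally, so column sums equal
#' per-gene mutated-sample counts over coding mutations.
#'
#' @param cohort A [cohort()].
#' @param genes A [gene_list()].
#' @param hotspot_only Restrict to hotspot protein changes; requires every
#'   panel gene to have a hotspot set.
#' @return Logical matrix, genes in rows (panel order), samples in columns
#'   (annotation order).
#' @export
binarize <- function(cohort, genes, hotspot_only = FALSE) {
  stopifnot(inherits(cohort, "cohort"), inherits(genes, "gene_list"))
  samples <- cohort$annotations$sample_id
  mat <- matrix(
    FALSE, nrow = length(genes$genes), ncol = length(samples),
    dimnames = list(genes$genes, samples)
  )
  if (length(genes$genes) == 0) return(mat)
  mut <- filter_nonsynonymous(cohort$mutations)
  mut <- dplyr::filter(mut, .data$gene %in% genes$genes)
  if (hotspot_only) {
    missing_hs <- setdiff(genes$genes, names(genes$hotspots))
    if (length(missing_hs) > 0) {
      abort(sprintf(
        "hotspot_only = TRUE but no hotspot set for gene(s): %s",
        paste(missing_hs, collapse = ", ")
      ))
    }
    mut <- dplyr::filter(
      mut,
      purrr::map2_lgl(
        .data$gene, .data$protein_change,
        function(g, pc) !is.na(pc) && pc %in% genes$hotspots[[g]]
      )
    )
  }
  if (nrow(mut) > 0) {
    mat[cbind(mut$gene, mut$sample_id)] <- TRUE
  }
  mat
}
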