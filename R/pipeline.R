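# End-to-end orchestration: read the two cohorts, run the power-gated
# frequency comparison, subtype cascade, clonality comparison, ddPCR calls
# and scalar summaries, and write one TSV per stage plus a run manifest.
# A thin command-line wrapper lives in inst/scripts/mutcohort-pipeline.R.

#' Assemble a pipeline run configuration
#'
#' @param exposed,control Named lists with paths `maf`, `seg`, `annotations`
#'   (or ready-made [cohort()] objects).
#' @param genes A [gene_list()] (or path to a one-column TSV of symbols with
#'   header `gene`).
#' @param catalog 96 x k signature catalog matrix, or path for
#'   [read_signature_catalog()]; `NULL` skips the subtype stage.
#' @param early_driver_genes Optional [gene_list()] for the clonality stage;
#'   defaults to `genes`.
#' @param ddpcr_wells Optional wells tibble or TSV path for the ddPCR stage.
#' @param n_tests Bonferroni divisor for the power gate.
#' @param sidedness Sidedness of the frequency comparison.
#' @param alpha Power-gate level.
#' @param shift Event shift for the clonality comparison.
#' @param n_exposed_cases Case count for the background-risk expectation;
#'   defaults to the exposed cohort size.
#' @param baseline_risk,treated_risk Background-risk parameters.
#' @param seed Global seed recorded in the manifest.
#' @param out_dir Output directory for the report tables.
#' @return A list of class `run_config`.
#' @export
run_config <- function(exposed, control, genes,
                       catalog = NULL,
                       early_driver_genes = NULL,
                       ddpcr_wells = NULL,
                       n_tests = NULL,
                       sidedness = "two_sided",
                       alpha = 0.05,
                       shift = 1L,
                       n_exposed_cases = NULL,
                       baseline_risk = 0.005,
                       treated_risk = 0.025,
                       seed = 1L,
                       out_dir = tempfile("mutcohort_run_")) {
  structure(
    list(
      exposed = exposed, control = control, genes = genes,
      catalog = catalog, early_driver_genes = early_driver_genes,
      ddpcr_wells = ddpcr_wells, n_tests = n_tests,
      sidedness = sidedness, alpha = alpha, shift = shift,
      n_exposed_cases = n_exposed_cases,
      baseline_risk = baseline_risk, treated_risk = treated_risk,
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

load_cohort_input <- function(x) {
  if (inherits(x, "cohort")) return(x)
  cohort(
    annotations = read_annotations(x$annotations),
    mutations = if (!is.null(x$maf)) read_maf(x$maf) else empty_mutations(),
    segments = if (!is.null(x$seg)) read_seg(x$seg) else empty_segments(),
    territory_mb = x$territory_mb %||% 37
  )
}

load_gene_input <- function(x) {
  if (inherits(x, "gene_list")) return(x)
  df <- readr::read_tsv(x, col_types = readr::cols(gene = readr::col_character()))
  check_required_cols(df, "gene", sprintf("gene list '%s'", x))
  gene_list(basename(x), df$gene)
}

write_stage <- function(df, out_dir, name, seed) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  writeLines(sprintf("# mutcohort stage=%s seed=%d", name, seed), path)
  suppressWarnings(readr::write_tsv(tibble::as_tibble(df), path, append = TRUE,
                                    col_names = TRUE))
  path
}

#' Run the full comparison pipeline
#'
#' Executes every stage that its inputs allow — power-gated frequency
#' comparison, power table, molecular subtyping, early-clonality comparison,
#' ddPCR calling, per-sample burden and the background-risk expectation —
#' writing one header-stamped TSV per stage into `config$out_dir` plus a
#' `manifest.tsv` recording parameters, seed and stage status. The manifest
#' is written even when a stage fails (with the failing stage recorded) and
#' the failure is then re-raised.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every stage result and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages_done <- character(0)
  current_stage <- "setup"
  results <- list()

  write_manifest <- function(status, failed_stage = NA_character_) {
    manifest <- tibble::tibble(
      key = c("package_version", "seed", "sidedness", "n_tests", "alpha",
              "status", "failed_stage", "stages_completed"),
      value = c(
        as.character(utils::packageVersion("mutcohort")),
        as.character(config$seed), config$sidedness,
        as.character(config$n_tests %||% NA), as.character(config$alpha),
        status, failed_stage, paste(stages_done, collapse = ",")
      )
    )
    readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  }

  run_stage <- function(name, expr) {
    current_stage <<- name
    value <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        write_manifest("failed", name)
        abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
      }),
      message = function(m) invokeRestart("muffleMessage")
    )
    stages_done <<- c(stages_done, name)
    value
  }

  exposed <- run_stage("load_exposed", load_cohort_input(config$exposed))
  control <- run_stage("load_control", load_cohort_input(config$control))
  genes <- run_stage("load_genes", load_gene_input(config$genes))
  n_tests <- config$n_tests %||% length(genes$genes)

  results$frequency <- run_stage("compare_freq", {
    cmp <- compare_gene_frequencies(
      exposed, control, genes,
      n_tests = n_tests, alpha = config$alpha, sidedness = config$sidedness
    )
    write_stage(cmp, config$out_dir, "frequency_comparison", config$seed)
    cmp
  })

  results$power <- run_stage("power", {
    pw <- powered_genes(
      dplyr::transmute(
        tibble::as_tibble(results$frequency),
        gene = .data$gene, n1 = .data$n1, n2 = .data$n2, m = .data$m
      ),
      n_tests = n_tests, alpha = config$alpha, sidedness = config$sidedness
    )
    write_stage(pw, config$out_dir, "power", config$seed)
    pw
  })

  if (!is.null(config$catalog)) {
    results$subtype <- run_stage("subtype", {
      catalog <- if (is.character(config$catalog)) {
        read_signature_catalog(config$catalog)
      } else {
        config$catalog
      }
      calls <- dplyr::bind_rows(
        classify_subtype(exposed, catalog),
        classify_subtype(control, catalog)
      )
      write_stage(calls, config$out_dir, "subtype", config$seed)
      calls
    })
  }

  results$clonality <- run_stage("clonality", {
    drivers <- config$early_driver_genes %||% genes
    cmp <- compare_early_counts(exposed, control, drivers, shift = config$shift)
    write_stage(cmp$histogram, config$out_dir, "clonality_histogram", config$seed)
    write_stage(glance(cmp), config$out_dir, "clonality_comparison", config$seed)
    cmp
  })

  if (!is.null(config$ddpcr_wells)) {
    results$ddpcr <- run_stage("ddpcr", {
      wells <- if (is.character(config$ddpcr_wells)) {
        readr::read_tsv(config$ddpcr_wells, col_types = readr::cols())
      } else {
        config$ddpcr_wells
      }
      calls <- call_ddpcr_wells(wells)
      write_stage(calls, config$out_dir, "ddpcr_calls", config$seed)
      calls
    })
  }

  results$burden <- run_stage("burden", {
    b <- dplyr::bind_rows(
      dplyr::mutate(mutation_burden_by_sample(exposed), cohort = "exposed"),
      dplyr::mutate(mutation_burden_by_sample(control), cohort = "control")
    )
    write_stage(b, config$out_dir, "burden", config$seed)
    b
  })

  results$background_risk <- run_stage("background_risk", {
    n_cases <- config$n_exposed_cases %||% nrow(exposed$annotations)
    bg <- expected_background_cases(
      n_cases, config$baseline_risk, config$treated_risk
    )
    write_stage(bg, config$out_dir, "background_risk", config$seed)
    bg
  })

  write_manifest("completed")
  results$out_dir <- config$out_dir
  invisible(results)
}
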