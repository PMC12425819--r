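# Seeded generator of paired exposed/control cohorts carrying the
# statistical structure the downstream analysis assumes: per-gene mutation
# frequencies, strata, purity, subtype-consistent copy-number segments,
# clonal/subclonal CCF mixtures, signature-derived trinucleotide contexts,
# WGD multiplicities and ddPCR droplet counts. One global seed drives a
# single random stream so sub-generators cannot desynchronize.

default_gene_probs <- function() {
  # emulates the discovery-cohort frequencies: strong PI3K-gene depletion in
  # the exposed cohort, comparable frequencies elsewhere
  tibble::tibble(
    gene = c("PIK3CA", "PIK3R1", "PTEN", "TP53", "ARID1A",
             "KRAS", "CTNNB1", "FGFR2"),
    p_exposed = c(0.14, 0.00, 0.67, 0.38, 0.48, 0.24, 0.24, 0.14),
    p_control = c(0.48, 0.31, 0.66, 0.38, 0.47, 0.19, 0.26, 0.12)
  )
}

#' Configuration for the synthetic cohort-pair generator
#'
#' Defaults emulate the study conditions of a small exposed cohort (n = 21)
#' against a large control cohort (n = 554): per-gene mutation probabilities
#' with PI3K-gene depletion in the exposed cohort, a TCGA-like subtype mix,
#' subtype-dependent deleted-genome fractions and mutation loads, a
#' clonal-dominant CCF mixture, and signature mixtures that make the planted
#' subtype recoverable by the classification cascade.
#'
#' @param n_exposed,n_control Cohort sizes.
#' @param gene_probs Tibble with `gene`, `p_exposed`, `p_control` columns.
#' @param hotspot_genes Named list mapping a gene to its hotspot protein
#'   changes; a mutation in such a gene takes a hotspot change with
#'   probability `hotspot_prob`.
#' @param hotspot_prob Probability that a mutation in a hotspot gene is a
#'   hotspot change (default 0.8, the approximate hotspot share of PIK3CA
#'   mutations in uterine cancer).
#' @param strata Named list (`exposed`, `control`) of histology sampling
#'   weights.
#' @param purity_bounds Uniform bounds for sample purity.
#' @param subtype_mix Named list (`exposed`, `control`) of proportions over
#'   POLE/MSI/CIN/GS; each must sum to 1.
#' @param deleted_fraction Named per-subtype target deleted-genome fraction.
#' @param passenger_mutations Named per-subtype expected passenger SNV count
#'   per sample (Poisson mean).
#' @param ccf_mixture List with `clonal_prob`, `noise_sd`,
#'   `subclonal_bounds`.
#' @param wgd_prob Probability a sample is genome-doubled.
#' @param pre_wgd_prob Probability a clonal mutation in a WGD sample predates
#'   the doubling (multiplicity 2).
#' @param signature_weights Named list (per subtype) of named signature
#'   mixing weights over the catalog columns.
#' @param catalog 96 x k signature catalog; default
#'   [synthetic_signature_catalog()] derived from the same seed.
#' @param genome_mb Copy-number genome territory in Mb.
#' @param territory_mb Coding territory in Mb (burden denominator).
#' @param ddpcr List with `droplets_per_well` and `true_af` (percent AF per
#'   planted positive well; zeros are negative wells).
#' @param seed Integer seed; all draws flow from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_exposed = 21,
                       n_control = 554,
                       gene_probs = default_gene_probs(),
                       hotspot_genes = list(
                         PIK3CA = c("p.E542K", "p.E545K", "p.H1047R")
                       ),
                       hotspot_prob = 0.8,
                       strata = list(
                         exposed = c(endometrioid = 0.7, serous = 0.2, other = 0.1),
                         control = c(endometrioid = 0.75, serous = 0.15, other = 0.1)
                       ),
                       purity_bounds = c(0.3, 0.9),
                       subtype_mix = list(
                         exposed = c(POLE = 0.07, MSI = 0.28, CIN = 0.26, GS = 0.39),
                         control = c(POLE = 0.07, MSI = 0.28, CIN = 0.26, GS = 0.39)
                       ),
                       deleted_fraction = c(POLE = 0.01, MSI = 0.01, CIN = 0.15, GS = 0.01),
                       passenger_mutations = c(POLE = 600, MSI = 300, CIN = 90, GS = 80),
                       ccf_mixture = list(
                         clonal_prob = 0.8, noise_sd = 0.01,
                         subclonal_bounds = c(0.05, 0.85)
                       ),
                       wgd_prob = 0.25,
                       pre_wgd_prob = 0.5,
                       signature_weights = list(
                         POLE = c(SBS10a = 0.6, SBS10b = 0.2, SBS1 = 0.2),
                         MSI = c(SBS6 = 0.4, SBS15 = 0.2, SBS44 = 0.2, SBS1 = 0.2),
                         CIN = c(SBS1 = 0.5, SBS5 = 0.5),
                         GS = c(SBS1 = 0.5, SBS5 = 0.5)
                       ),
                       catalog = NULL,
                       genome_mb = 3000,
                       territory_mb = 37,
                       ddpcr = list(droplets_per_well = 10000,
                                    true_af = c(5, 5, 5, rep(0, 36))),
                       seed = 1L) {
  if (n_exposed < 1 || n_control < 1) abort("cohort sizes must be >= 1")
  check_required_cols(gene_probs, c("gene", "p_exposed", "p_control"), "gene_probs")
  if (nrow(gene_probs) == 0) abort("sim_config: need at least one gene")
  probs <- c(gene_probs$p_exposed, gene_probs$p_control)
  if (any(probs < 0 | probs > 1)) abort("gene probabilities must be in [0, 1]")
  for (mix in subtype_mix) {
    if (abs(sum(mix) - 1) > 1e-9) abort("subtype proportions must sum to 1")
  }
  if (is.null(catalog)) catalog <- synthetic_signature_catalog(seed)
  structure(
    list(
      n_exposed = n_exposed, n_control = n_control,
      gene_probs = gene_probs, hotspot_genes = hotspot_genes,
      hotspot_prob = hotspot_prob, strata = strata,
      purity_bounds = purity_bounds, subtype_mix = subtype_mix,
      deleted_fraction = deleted_fraction,
      passenger_mutations = passenger_mutations,
      ccf_mixture = ccf_mixture, wgd_prob = wgd_prob,
      pre_wgd_prob = pre_wgd_prob,
      signature_weights = signature_weights, catalog = catalog,
      genome_mb = genome_mb, territory_mb = territory_mb,
      ddpcr = ddpcr, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Synthetic 96-channel signature catalog
#'
#' A clearly synthetic stand-in for a COSMIC-style SBS catalog: 13 profiles
#' carrying the names the subtype cascade expects, each concentrating most of
#' its mass on its own sparse random channel subset over a small flat
#' background. Columns sum to 1; fully determined by the seed. Intended for
#' simulation and testing only — real analyses should load a published
#' catalog via [read_signature_catalog()].
#'
#' @param seed Integer seed.
#' @param signatures Signature names (default the 13 signatures used by the
#'   subtype cascade plus common background processes).
#' @return 96 x length(signatures) matrix with columns summing to 1.
#' @export
synthetic_signature_catalog <- function(seed = 42L,
                                        signatures = c(
                                          "SBS1", "SBS5", "SBS6", "SBS10a",
                                          "SBS10b", "SBS14", "SBS15", "SBS18",
                                          "SBS20", "SBS21", "SBS26", "SBS40",
                                          "SBS44"
                                        )) {
  withr::with_seed(as.integer(seed), {
    k <- length(signatures)
    mat <- matrix(0.02 / 96, nrow = 96, ncol = k,
                  dimnames = list(sbs96_channels(), signatures))
    for (j in seq_len(k)) {
      peaks <- sample.int(96, 8)
      w <- runif(8)
      mat[peaks, j] <- mat[peaks, j] + 0.98 * w / sum(w)
    }
    sweep(mat, 2, colSums(mat), "/")
  })
}

# ---- internal single-stream draw helpers (no seeding) ----

draw_ccfs <- function(n_clonal, n_subclonal, noise_sd, subclonal_bounds,
                      threshold = 0.95, margin = 0.02) {
  clonal <- if (n_clonal > 0) {
    pmax(threshold, pmin(1, 1 - abs(rnorm(n_clonal, 0, noise_sd))))
  } else {
    numeric(0)
  }
  upper <- min(subclonal_bounds[2], threshold - margin)
  subclonal <- if (n_subclonal > 0) {
    runif(n_subclonal, subclonal_bounds[1], upper)
  } else {
    numeric(0)
  }
  sample(c(clonal, subclonal))
}

draw_counts96 <- function(catalog, weights, total) {
  catalog <- validate_catalog(catalog)
  w <- setNames(numeric(ncol(catalog)), colnames(catalog))
  w[names(weights)] <- weights
  if (any(w < 0)) abort("signature weights must be nonnegative")
  if (sum(w) == 0) abort("signature weights must not all be zero")
  prob <- as.numeric(catalog %*% (w / sum(w)))
  if (total == 0) return(setNames(integer(96), rownames(catalog)))
  setNames(as.integer(rmultinom(1, total, prob)), rownames(catalog))
}

draw_segments <- function(target_deleted_fraction, purity, genome_mb,
                          r1 = 0.36, sample_id = "S1") {
  if (target_deleted_fraction < 0 || target_deleted_fraction > 1) {
    abort("target deleted fraction must be in [0, 1]")
  }
  deleted_mb <- round(target_deleted_fraction * genome_mb)
  del_value <- -(r1 * purity + 0.2)
  if (deleted_mb == 0) {
    return(tibble::tibble(
      sample_id = sample_id, chromosome = "1",
      start = 1, end = genome_mb * 1e6, seg_value = 0, n_probes = NA_integer_
    ))
  }
  n_del <- max(1L, ceiling(deleted_mb / 25))
  sizes <- rep(floor(deleted_mb / n_del), n_del)
  sizes[seq_len(deleted_mb - sum(sizes))] <- sizes[seq_len(deleted_mb - sum(sizes))] + 1
  sizes <- sizes[sizes > 0]
  neutral_mb <- genome_mb - deleted_mb
  gaps <- rep(floor(neutral_mb / (length(sizes) + 1)), length(sizes) + 1)
  gaps[1] <- gaps[1] + (neutral_mb - sum(gaps))
  segs <- list()
  pos <- 1
  for (i in seq_along(sizes)) {
    if (gaps[i] > 0) {
      segs[[length(segs) + 1]] <- c(pos, pos + gaps[i] * 1e6 - 1, 0)
      pos <- pos + gaps[i] * 1e6
    }
    segs[[length(segs) + 1]] <- c(pos, pos + sizes[i] * 1e6 - 1, del_value)
    pos <- pos + sizes[i] * 1e6
  }
  last_gap <- gaps[length(gaps)]
  if (last_gap > 0) {
    segs[[length(segs) + 1]] <- c(pos, pos + last_gap * 1e6 - 1, 0)
  }
  m <- do.call(rbind, segs)
  tibble::tibble(
    sample_id = sample_id, chromosome = "1",
    start = m[, 1], end = m[, 2], seg_value = m[, 3], n_probes = NA_integer_
  )
}

# decode a pyrimidine-strand channel label into (ref, alt, context)
channel_to_alleles <- function(channel) {
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  ctx <- paste0(substr(channel, 1, 1), ref, substr(channel, 7, 7))
  list(ref = ref, alt = alt, context = ctx)
}

random_protein_change <- function(n) {
  pos <- sample.int(800, n, replace = TRUE)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  list(
    change = paste0("p.", sample(aa, n, TRUE), pos, sample(aa, n, TRUE)),
    position = pos
  )
}

# ---- exported seeded generators ----

#' Simulate clonal/subclonal cancer cell fractions
#'
#' Clonal values sit at or above the clonality threshold (1 minus truncated
#' Gaussian noise); subclonal values are uniform on bounds kept below
#' `threshold - margin`, so the planted labels are always recoverable by the
#' threshold rule. Order is randomized.
#'
#' @param n_clonal,n_subclonal Counts of planted clonal/subclonal mutations.
#' @param noise_sd Gaussian noise SD on the clonal CCFs.
#' @param subclonal_bounds Uniform bounds for subclonal CCFs.
#' @param threshold Clonality threshold (default 0.95).
#' @param seed Integer seed.
#' @return Numeric vector of CCFs of length `n_clonal + n_subclonal`.
#' @export
simulate_ccfs <- function(n_clonal, n_subclonal, noise_sd = 0.01,
                          subclonal_bounds = c(0.05, 0.85),
                          threshold = 0.95, seed = 1L) {
  if (n_clonal < 0 || n_subclonal < 0) abort("counts must be >= 0")
  withr::with_seed(as.integer(seed), {
    draw_ccfs(n_clonal, n_subclonal, noise_sd, subclonal_bounds, threshold)
  })
}

#' Simulate a 96-channel mutation spectrum from a signature mixture
#'
#' A multinomial draw of `total` mutations from the mixture distribution
#' `catalog %*% weights` (normalized).
#'
#' @param catalog 96 x k signature catalog.
#' @param weights Named nonnegative mixing weights over catalog columns.
#' @param total Total mutation count.
#' @param seed Integer seed.
#' @return Named integer vector over [sbs96_channels()].
#' @export
simulate_counts96 <- function(catalog, weights, total, seed = 1L) {
  withr::with_seed(as.integer(seed), draw_counts96(catalog, weights, total))
}

#' Simulate copy-number segments with a planted deleted fraction
#'
#' Builds non-overlapping segments covering `genome_mb` megabases in which
#' the deleted segments (seg_value safely below `-r1 * purity`) span the
#' target fraction of the genome up to 1-Mb granularity.
#'
#' @param target_deleted_fraction Target deleted genome fraction in \[0, 1\].
#' @param purity Sample purity in (0, 1].
#' @param genome_mb Genome territory in Mb.
#' @param r1 Deletion amplitude threshold the segments must clear.
#' @param sample_id Sample label for the segment rows.
#' @param seed Integer seed (layout is deterministic; kept for interface
#'   symmetry).
#' @return Tibble of segments.
#' @export
simulate_segments <- function(target_deleted_fraction, purity,
                              genome_mb = 3000, r1 = 0.36,
                              sample_id = "S1", seed = 1L) {
  withr::with_seed(as.integer(seed), {
    draw_segments(target_deleted_fraction, purity, genome_mb, r1, sample_id)
  })
}

#' Simulate a 2x2 contingency table from two binomial groups
#'
#' @param n1,n2 Group sizes.
#' @param p1,p2 Per-sample success probabilities.
#' @param seed Integer seed.
#' @return A [contingency_table()] with groups in rows and
#'   (success, failure) columns.
#' @export
simulate_table <- function(n1, n2, p1, p2, seed = 1L) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1)) abort("probabilities must be in [0, 1]")
  withr::with_seed(as.integer(seed), {
    k1 <- rbinom(1, n1, p1)
    k2 <- rbinom(1, n2, p2)
    contingency_table(
      matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE),
      row_labels = c("group1", "group2"),
      col_labels = c("mutated", "wildtype")
    )
  })
}

#' Simulate ddPCR droplet counts for a plate of wells
#'
#' Each well with a planted allele fraction draws its mutant droplet count
#' binomially at that fraction; zero-AF wells are true negatives.
#'
#' @param true_af Vector of planted allele fractions in percent (0 for
#'   negative wells); one well per entry.
#' @param droplets_per_well Total droplets per well.
#' @param assay Assay label.
#' @param seed Integer seed.
#' @return Wells tibble (`sample_id`, `assay`, `mutant_droplets`,
#'   `wildtype_droplets`) ready for [call_ddpcr_wells()].
#' @export
simulate_ddpcr <- function(true_af, droplets_per_well = 10000,
                           assay = "PIK3CA_hotspot", seed = 1L) {
  if (any(true_af < 0 | true_af > 100)) abort("true_af must be in [0, 100] percent")
  withr::with_seed(as.integer(seed), {
    mut <- rbinom(length(true_af), droplets_per_well, true_af / 100)
    tibble::tibble(
      sample_id = sprintf("W%03d", seq_along(true_af)),
      assay = assay,
      mutant_droplets = mut,
      wildtype_droplets = droplets_per_well - mut
    )
  })
}

simulate_one_cohort <- function(config, label, n, prefix) {
  gene_probs <- config$gene_probs
  p <- if (label == "exposed") gene_probs$p_exposed else gene_probs$p_control
  mix <- config$subtype_mix[[label]]
  strata <- config$strata[[label]]
  ids <- sprintf("%s%03d", prefix, seq_len(n))

  subtype <- sample(names(mix), n, TRUE, prob = mix)
  purity <- runif(n, config$purity_bounds[1], config$purity_bounds[2])
  wgd <- runif(n) < config$wgd_prob
  histology <- sample(names(strata), n, TRUE, prob = strata)

  annotations <- tibble::tibble(
    sample_id = ids,
    cohort = label,
    purity = purity,
    ploidy = ifelse(wgd, 3.8, 2.0),
    wgd = wgd,
    histology = histology,
    grade = sample(c("1", "2", "3"), n, TRUE),
    tamoxifen_years = if (label == "exposed") round(runif(n, 0.5, 8), 1) else NA_real_,
    msi_flag = subtype == "MSI",
    bmi = round(rnorm(n, 28, 4), 1)
  )

  driver_hits <- matrix(
    runif(n * nrow(gene_probs)) < rep(p, each = n),
    nrow = n
  )

  mutations <- purrr::map(seq_len(n), function(i) {
    st <- subtype[i]
    driver_genes <- gene_probs$gene[driver_hits[i, ]]
    if (st == "POLE") driver_genes <- c(driver_genes, "POLE")
    n_passenger <- stats::rpois(1, config$passenger_mutations[[st]])
    genes <- c(driver_genes,
               if (n_passenger > 0) sprintf("PSG%04d", sample.int(9999, n_passenger, TRUE)))
    n_mut <- length(genes)
    if (n_mut == 0) return(empty_mutations())
    weights <- config$signature_weights[[st]]
    prob <- as.numeric(config$catalog %*% {
      w <- setNames(numeric(ncol(config$catalog)), colnames(config$catalog))
      w[names(weights)] <- weights
      w / sum(w)
    })
    channels <- sample(sbs96_channels(), n_mut, TRUE, prob = prob)
    al <- channel_to_alleles(channels)
    is_clonal <- runif(n_mut) < config$ccf_mixture$clonal_prob
    ccf <- numeric(n_mut)
    ccf[is_clonal] <- pmax(0.95, pmin(1, 1 - abs(
      rnorm(sum(is_clonal), 0, config$ccf_mixture$noise_sd)
    )))
    ccf[!is_clonal] <- runif(
      sum(!is_clonal),
      config$ccf_mixture$subclonal_bounds[1],
      min(config$ccf_mixture$subclonal_bounds[2], 0.93)
    )
    multiplicity <- rep(1L, n_mut)
    if (wgd[i]) {
      pre <- is_clonal & (runif(n_mut) < config$pre_wgd_prob)
      multiplicity[pre] <- 2L
    }
    pc <- random_protein_change(n_mut)
    # hotspot genes take a hotspot change with the configured probability;
    # a planted POLE driver always lands in the exonuclease domain
    for (j in seq_len(n_mut)) {
      g <- genes[j]
      if (g %in% names(config$hotspot_genes) &&
          runif(1) < config$hotspot_prob) {
        pc$change[j] <- sample(config$hotspot_genes[[g]], 1)
        pc$position[j] <- as.integer(gsub("\\D", "", pc$change[j]))
      }
      if (g == "POLE" && j <= length(driver_genes)) {
        pc$position[j] <- sample(268:471, 1)
        pc$change[j] <- sprintf("p.P%dR", pc$position[j])
      }
    }
    tibble::tibble(
      sample_id = ids[i],
      gene = genes,
      chromosome = as.character(sample.int(22, n_mut, TRUE)),
      start = sample.int(2e8, n_mut, TRUE),
      ref_allele = al$ref,
      alt_allele = al$alt,
      variant_classification = "Missense_Mutation",
      protein_change = pc$change,
      protein_position = as.integer(pc$position),
      trinucleotide_context = al$context,
      ccf = ccf,
      multiplicity = multiplicity
    )
  }) |> dplyr::bind_rows()

  segments <- purrr::map(seq_len(n), function(i) {
    draw_segments(
      config$deleted_fraction[[subtype[i]]], purity[i],
      config$genome_mb, sample_id = ids[i]
    )
  }) |> dplyr::bind_rows()

  list(
    cohort = cohort(annotations, mutations, segments, config$territory_mb),
    subtype = setNames(subtype, ids)
  )
}

#' Simulate a paired exposed/control cohort
#'
#' Draws both cohorts from a [sim_config()]: per-sample gene mutation
#' indicators are independent Bernoulli draws at the configured per-cohort
#' probabilities; each sample gets a stratum, purity, molecular subtype with
#' matching signature mixture, segments at the subtype's deleted fraction,
#' CCFs from the clonal/subclonal mixture and WGD-consistent multiplicities.
#' Fully reproducible given the config seed; the planted per-sample subtypes
#' are returned for recovery checks.
#'
#' @param config A [sim_config()].
#' @return List with `exposed` and `control` [cohort()]s plus
#'   `truth` (a tibble with the planted subtype per sample) and `config`.
#' @export
simulate_cohort_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    exp_res <- simulate_one_cohort(config, "exposed", config$n_exposed, "TA")
    ctl_res <- simulate_one_cohort(config, "control", config$n_control, "DN")
    list(
      exposed = exp_res$cohort,
      control = ctl_res$cohort,
      truth = tibble::tibble(
        sample_id = c(names(exp_res$subtype), names(ctl_res$subtype)),
        subtype = c(unname(exp_res$subtype), unname(ctl_res$subtype))
      ),
      config = config
    )
  })
}

#' Write a simulated cohort to MAF/SEG/annotation fixtures
#'
#' Emits the exact dialects the readers consume, so round-trip tests and the
#' pipeline exercise the real I/O path.
#'
#' @param cohort A [cohort()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_cohort_fixtures <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    maf = file.path(dir, paste0(prefix, ".maf.tsv")),
    seg = file.path(dir, paste0(prefix, ".seg.tsv")),
    annotations = file.path(dir, paste0(prefix, ".annotations.tsv"))
  )
  write_maf(cohort$mutations, paths["maf"])
  write_seg(cohort$segments, paths["seg"])
  write_annotations(cohort$annotations, paths["annotations"])
  invisible(paths)
}
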