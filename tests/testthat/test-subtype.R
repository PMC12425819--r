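make_snv <- function(sample = "S1", gene = "PSG1", ref = "C", alt = "T",
                     ctx = "ACA", class = "Missense_Mutation",
                     protein_position = NA_integer_) {
  tibble::tibble(
    sample_id = sample, gene = gene, chromosome = "1", start = 100L,
    ref_allele = ref, alt_allele = alt, variant_classification = class,
    protein_change = NA_character_,
    protein_position = as.integer(protein_position),
    trinucleotide_context = ctx, ccf = NA_real_, multiplicity = NA_integer_
  )
}

test_that("sbs96_vector tallies channels with pyrimidine-strand collapse", {
  expect_equal(sum(sbs96_vector(empty_mutations())), 0)

  one <- sbs96_vector(make_snv(ref = "C", alt = "T", ctx = "ACA"))
  expect_equal(sum(one), 1)
  expect_equal(unname(one["A[C>T]A"]), 1L)

  # purine-strand record folds onto the reverse complement channel:
  # G>A in TGT == C>T in ACA
  flipped <- sbs96_vector(make_snv(ref = "G", alt = "A", ctx = "TGT"))
  expect_equal(unname(flipped["A[C>T]A"]), 1L)

  # hand-assigned 10-record fixture
  recs <- dplyr::bind_rows(
    make_snv(ref = "C", alt = "A", ctx = "ACG"),
    make_snv(ref = "C", alt = "A", ctx = "ACG"),
    make_snv(ref = "T", alt = "G", ctx = "GTC"),
    make_snv(ref = "C", alt = "T", ctx = "TCT"),
    make_snv(ref = "T", alt = "C", ctx = "ATA"),
    make_snv(ref = "G", alt = "C", ctx = "AGA"), # -> T[C>G]T
    make_snv(ref = "A", alt = "T", ctx = "CAC"), # -> G[T>A]G
    make_snv(ref = "C", alt = "G", ctx = "CCC"),
    make_snv(ref = "T", alt = "A", ctx = "TTT"),
    make_snv(ref = "C", alt = "T", ctx = "GCG")
  )
  v <- sbs96_vector(recs)
  expect_equal(sum(v), 10)
  expect_equal(unname(v["A[C>A]G"]), 2L)
  expect_equal(unname(v["G[T>G]C"]), 1L)
  expect_equal(unname(v["T[C>G]T"]), 1L)
  expect_equal(unname(v["G[T>A]G"]), 1L)

  # non-SNVs are skipped with a message
  indel <- make_snv(ref = "CT", alt = "C", ctx = "ACT")
  expect_message(v2 <- sbs96_vector(dplyr::bind_rows(recs, indel)), "skipped")
  expect_equal(sum(v2), 10)

  # inconsistent context is an error
  expect_error(sbs96_vector(make_snv(ref = "C", alt = "T", ctx = "ATA")),
               "inconsistent")
})

test_that("nnls_exposures recovers exact mixtures and flags collinearity honestly", {
  catalog <- synthetic_signature_catalog(seed = 14)
  # pure column
  pure <- nnls_exposures(100 * catalog[, "SBS10a"], catalog)
  expect_equal(pure$exposure[pure$signature == "SBS10a"], 100, tolerance = 1e-6)
  expect_lt(attr(pure, "residual"), 1e-9)
  expect_equal(sum(pure$exposure[pure$signature != "SBS10a"]), 0, tolerance = 1e-6)

  # duplicated column: only the sum of the pair is identifiable
  dup <- cbind(catalog, DUP = catalog[, "SBS1"])
  mix <- nnls_exposures(80 * catalog[, "SBS1"], dup)
  expect_equal(sum(mix$exposure[mix$signature %in% c("SBS1", "DUP")]), 80,
               tolerance = 1e-6)

  # scale equivariance
  counts <- as.numeric(catalog %*% setNames(
    c(60, 40, rep(0, ncol(catalog) - 2)), colnames(catalog)
  ))
  e1 <- nnls_exposures(counts, catalog)
  e2 <- nnls_exposures(2 * counts, catalog)
  expect_equal(e2$exposure, 2 * e1$exposure, tolerance = 1e-6)

  expect_warning(zero <- nnls_exposures(rep(0, 96), catalog), "zero")
  expect_equal(sum(zero$exposure), 0)
})

test_that("catalog validation and the catalog reader enforce the contract", {
  catalog <- synthetic_signature_catalog(seed = 3)
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(
    tibble::as_tibble(catalog) |> dplyr::mutate(channel = rownames(catalog),
                                                .before = 1),
    path
  )
  back <- read_signature_catalog(path)
  expect_equal(back, catalog, tolerance = 1e-12)
  bad <- catalog
  bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(nnls_exposures(rep(1, 96), bad), "sum to 1")
})

test_that("classify_pole needs both a domain mutation and signature support", {
  catalog <- synthetic_signature_catalog(seed = 5)
  params <- subtype_params()
  strong <- nnls_exposures(round(500 * catalog[, "SBS10a"]), catalog)
  weak <- nnls_exposures(round(500 * catalog[, "SBS1"]), catalog)
  domain_mut <- make_snv(gene = "POLE", protein_position = 286)
  outside_mut <- make_snv(gene = "POLE", protein_position = 100)
  silent_domain <- make_snv(gene = "POLE", protein_position = 286, class = "Silent")

  expect_true(classify_pole(domain_mut, strong, params))
  expect_false(classify_pole(outside_mut, strong, params))
  expect_false(classify_pole(domain_mut, weak, params))
  expect_false(classify_pole(silent_domain, strong, params))
})

test_that("classify_msi honors the flag first and signatures otherwise", {
  catalog <- synthetic_signature_catalog(seed = 5)
  params <- subtype_params()
  msi_exp <- nnls_exposures(round(400 * catalog[, "SBS6"]), catalog)
  none <- nnls_exposures(round(400 * catalog[, "SBS1"]), catalog)
  expect_true(classify_msi(list(msi_flag = TRUE), none, params))
  expect_false(classify_msi(list(msi_flag = FALSE), msi_exp, params))
  expect_true(classify_msi(list(msi_flag = NA), msi_exp, params))
  expect_false(classify_msi(list(msi_flag = NA), none, params))
})

test_that("deleted_genome_fraction applies the purity-scaled inclusive threshold", {
  seg <- function(len_mb, value) {
    tibble::tibble(sample_id = "S1", chromosome = "1", start = 1,
                   end = len_mb * 1e6, seg_value = value,
                   n_probes = NA_integer_)
  }
  two <- dplyr::bind_rows(
    seg(25, -0.5),
    dplyr::mutate(seg(75, 0), start = 25e6 + 1, end = 100e6)
  )
  expect_equal(deleted_genome_fraction(two, purity = 1), 0.25)
  # boundary inclusive at exactly -r1 * purity
  purity <- 0.5
  boundary <- dplyr::bind_rows(
    seg(10, -0.36 * purity),
    dplyr::mutate(seg(90, 0), start = 10e6 + 1, end = 100e6)
  )
  expect_equal(deleted_genome_fraction(boundary, purity), 0.1)
  # a deletion just above the full-purity threshold still counts at low purity
  mid <- dplyr::bind_rows(
    seg(10, -0.2),
    dplyr::mutate(seg(90, 0), start = 10e6 + 1, end = 100e6)
  )
  expect_equal(deleted_genome_fraction(mid, purity = 1), 0)
  expect_equal(deleted_genome_fraction(mid, purity = 0.5), 0.1)
  # purity monotonicity: lowering purity never decreases the fraction
  for (v in c(-0.1, -0.3, -0.6)) {
    s <- dplyr::bind_rows(
      seg(30, v), dplyr::mutate(seg(70, 0), start = 30e6 + 1, end = 100e6)
    )
    fr <- vapply(c(1, 0.8, 0.5, 0.2), function(p) deleted_genome_fraction(s, p),
                 numeric(1))
    expect_true(all(diff(fr) >= 0))
  }
  expect_error(deleted_genome_fraction(two[0, ], 0.5), "territory")
  expect_error(deleted_genome_fraction(two, 0), "purity")
})

test_that("the cascade assigns exactly one subtype with the stated precedence", {
  catalog <- synthetic_signature_catalog(seed = 31)
  params <- subtype_params()

  ann <- tibble::tibble(
    sample_id = c("POLE1", "MSI1", "CIN1", "GS1", "BOTH1"),
    cohort = "exposed", purity = 0.8, ploidy = 2, wgd = FALSE,
    histology = "endometrioid", grade = "2", tamoxifen_years = NA_real_,
    msi_flag = c(FALSE, TRUE, FALSE, FALSE, TRUE), bmi = NA_real_
  )
  ctx_mut <- function(sample, weights, n = 300) {
    counts <- simulate_counts96(catalog, weights, n, seed = 17)
    channels <- rep(names(counts), counts)
    al <- mutcohort:::channel_to_alleles(channels)
    tibble::tibble(
      sample_id = sample, gene = sprintf("PSG%d", seq_along(channels)),
      chromosome = "1", start = seq_along(channels),
      ref_allele = al$ref, alt_allele = al$alt,
      variant_classification = "Missense_Mutation",
      protein_change = NA_character_, protein_position = NA_integer_,
      trinucleotide_context = al$context, ccf = NA_real_,
      multiplicity = NA_integer_
    )
  }
  pole_mut <- make_snv(sample = "POLE1", gene = "POLE", protein_position = 286)
  both_mut <- make_snv(sample = "BOTH1", gene = "POLE", protein_position = 300)
  mut <- dplyr::bind_rows(
    ctx_mut("POLE1", c(SBS10a = 1)), pole_mut,
    ctx_mut("MSI1", c(SBS6 = 1)),
    ctx_mut("CIN1", c(SBS1 = 1)),
    ctx_mut("GS1", c(SBS1 = 1)),
    ctx_mut("BOTH1", c(SBS10a = 0.5, SBS6 = 0.5)), both_mut
  )
  segs <- dplyr::bind_rows(
    simulate_segments(0.01, 0.8, 1000, sample_id = "POLE1"),
    simulate_segments(0.01, 0.8, 1000, sample_id = "MSI1"),
    simulate_segments(0.05, 0.8, 1000, sample_id = "CIN1"),
    simulate_segments(0.01, 0.8, 1000, sample_id = "GS1"),
    simulate_segments(0.01, 0.8, 1000, sample_id = "BOTH1")
  )
  co <- cohort(ann, mut, segs)
  calls <- suppressMessages(classify_subtype(co, catalog, params))
  expect_equal(
    calls$subtype[match(c("POLE1", "MSI1", "CIN1", "GS1", "BOTH1"),
                        calls$sample_id)],
    c("POLE", "MSI", "CIN", "GS", "POLE")
  )
  # total function: every sample gets exactly one of the four labels
  expect_equal(nrow(calls), nrow(ann))
  expect_true(all(calls$subtype %in% c("POLE", "MSI", "CIN", "GS")))
  # CIN/GS split at r2: deleted fraction 0.05 -> CIN, 0.01 -> GS
  expect_gt(calls$deleted_fraction[calls$sample_id == "CIN1"], params$r2)
  expect_lte(calls$deleted_fraction[calls$sample_id == "GS1"], params$r2)
})

test_that("subtype_params validates thresholds", {
  expect_error(subtype_params(r1 = 0), "positive")
  expect_error(subtype_params(signature_fraction_threshold = 1.5), "in \\(0, 1\\)")
})
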