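test_that("read_maf parses fixtures, types optional columns and guards the vocabulary", {
  # header-only file -> empty table
  empty <- read_maf(write_lines_tsv(maf_header))
  expect_equal(nrow(empty), 0)

  path <- write_lines_tsv(c(
    maf_header,
    maf_row("S1", "PIK3CA", "Silent"),
    maf_row("S2", "PTEN", "Missense_Mutation", start = 200),
    maf_row("S3", "TP53", "Intron", start = 300)
  ))
  mut <- read_maf(path)
  expect_equal(nrow(mut), 3)
  expect_equal(mut$variant_classification,
               c("Silent", "Missense_Mutation", "Intron"))
  expect_type(mut$start, "integer")
  expect_true(all(is.na(mut$ccf)))

  # classification outside the controlled set
  bad <- write_lines_tsv(c(maf_header, maf_row("S1", "PTEN", "Splice_Region")))
  expect_error(read_maf(bad), "Splice_Region")

  # missing required column named in the error
  noclass <- write_lines_tsv(paste("sample_id", "gene", sep = "\t"))
  expect_error(read_maf(noclass), "variant_classification")

  # unparseable position reported with its line number
  badpos <- write_lines_tsv(c(maf_header, maf_row("S1", "PTEN",
                                                  "Missense_Mutation",
                                                  start = "12x4")))
  expect_error(read_maf(badpos), "line")

  # duplicates collapsed with a warning
  dup <- write_lines_tsv(c(
    maf_header,
    maf_row("S1", "PTEN", "Missense_Mutation"),
    maf_row("S1", "PTEN", "Missense_Mutation")
  ))
  expect_warning(out <- read_maf(dup), "duplicate")
  expect_equal(nrow(out), 1)
})

test_that("read_seg validates coordinates and reproduces segment lengths", {
  header <- paste("sample_id", "chromosome", "start", "end", "seg_value", sep = "\t")
  expect_equal(nrow(read_seg(write_lines_tsv(header))), 0)

  path <- write_lines_tsv(c(
    header,
    paste("S1", "1", 1, 10e6, -0.5, sep = "\t"),
    paste("S1", "1", 10e6 + 1, 40e6, 0.1, sep = "\t")
  ))
  seg <- read_seg(path)
  expect_equal(seg$end - seg$start + 1, c(10e6, 30e6))

  rev_order <- write_lines_tsv(c(header, paste("S1", "1", 100, 50, 0, sep = "\t")))
  expect_error(read_seg(rev_order), "start > end")

  overlap <- write_lines_tsv(c(
    header,
    paste("S1", "1", 1, 100, 0, sep = "\t"),
    paste("S1", "1", 50, 200, 0, sep = "\t")
  ))
  expect_error(read_seg(overlap), "overlap")
})

test_that("read_annotations types booleans flexibly and guards purity and cohort", {
  header <- paste("sample_id", "cohort", "purity", "wgd", "msi_flag", sep = "\t")
  path <- write_lines_tsv(c(
    header,
    paste("S1", "exposed", 0.8, "Yes", "0", sep = "\t"),
    paste("S2", "control", 0.5, "false", "TRUE", sep = "\t")
  ))
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$wgd, c(TRUE, FALSE))
  expect_equal(ann$msi_flag, c(FALSE, TRUE))

  badp <- write_lines_tsv(c(header, paste("S1", "exposed", 1.5, "0", "0", sep = "\t")))
  expect_error(read_annotations(badp), "purity")

  badc <- write_lines_tsv(c(header, paste("S1", "treated", 0.5, "0", "0", sep = "\t")))
  expect_error(read_annotations(badc), "cohort")
})

test_that("all three formats round-trip through write/read unchanged", {
  sim <- simulate_cohort_pair(tiny_sim_config(seed = 11, n_exposed = 6, n_control = 6))
  co <- sim$exposed
  dir <- tempfile()
  paths <- write_cohort_fixtures(co, dir)
  expect_equal(read_maf(paths["maf"]), co$mutations, ignore_attr = TRUE)
  expect_equal(read_seg(paths["seg"]), co$segments, ignore_attr = TRUE)
  expect_equal(read_annotations(paths["annotations"]), co$annotations,
               ignore_attr = TRUE)
})

test_that("filter_nonsynonymous removes exactly the noncoding classes, idempotently", {
  classes <- c(
    "Missense_Mutation", "Silent", "3'UTR", "5'UTR", "IGR", "Intron",
    "lincRNA", "RNA", "Nonsense_Mutation", "Frame_Shift_Del"
  )
  mut <- empty_mutations() |>
    dplyr::bind_rows(tibble::tibble(
      sample_id = sprintf("S%d", seq_along(classes)), gene = "PTEN",
      chromosome = "1", start = seq_along(classes), ref_allele = "C",
      alt_allele = "T", variant_classification = classes
    ))
  kept <- filter_nonsynonymous(mut)
  expect_equal(nrow(kept), 3)
  expect_setequal(
    kept$variant_classification,
    c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del")
  )
  # set-filter, idempotent, order preserved
  expect_true(all(kept$sample_id %in% mut$sample_id))
  expect_equal(filter_nonsynonymous(kept), kept, ignore_attr = TRUE)
  expect_equal(kept$start, sort(kept$start))
  # a single Silent record filters to nothing; empty input stays empty
  expect_equal(nrow(filter_nonsynonymous(mut[mut$variant_classification == "Silent", ])), 0)
  expect_equal(nrow(filter_nonsynonymous(empty_mutations())), 0)
})

test_that("binarize collapses to indicators whose marginals match planted counts", {
  counts <- c(PIK3CA = 4, PTEN = 7, TP53 = 0)
  co <- make_count_cohort(counts, n = 10, label = "exposed")
  gl <- gene_list("panel", names(counts))
  mat <- binarize(co, gl)
  expect_equal(dim(mat), c(3, 10))
  expect_equal(rowSums(mat), counts)

  # two records in the same gene/sample collapse to one TRUE entry
  co2 <- co
  extra <- co$mutations[co$mutations$gene == "PIK3CA", ][1, ]
  extra$start <- 99L
  co2$mutations <- dplyr::bind_rows(co$mutations, extra)
  expect_equal(binarize(co2, gl), mat)

  # empty gene list -> 0-row matrix
  expect_equal(nrow(binarize(co, gene_list("empty", character(0)))), 0)

  # hotspot mode restricts to hotspot protein changes and demands a hotspot set
  hs_mut <- co$mutations
  hs_mut$protein_change <- ifelse(
    hs_mut$gene == "PIK3CA" & hs_mut$sample_id %in% c("exposed001", "exposed002"),
    "p.E545K", "p.A100B"
  )
  co3 <- cohort(co$annotations, hs_mut)
  gl_hs <- gene_list("panel", "PIK3CA", hotspots = list(PIK3CA = c("p.E545K")))
  expect_equal(sum(binarize(co3, gl_hs, hotspot_only = TRUE)), 2)
  expect_error(binarize(co3, gene_list("p", "PIK3CA"), hotspot_only = TRUE),
               "hotspot")
})

test_that("cohort() enforces referential integrity and gene_list rejects duplicates", {
  ann <- tibble::tibble(sample_id = "S1", cohort = "exposed", purity = 0.5)
  orphan <- empty_mutations() |>
    dplyr::bind_rows(tibble::tibble(
      sample_id = "GHOST", gene = "PTEN", chromosome = "1", start = 1L,
      ref_allele = "C", alt_allele = "T",
      variant_classification = "Missense_Mutation"
    ))
  expect_error(cohort(ann, orphan), "GHOST")
  expect_error(cohort(ann, territory_mb = 0), "territory")
  expect_error(gene_list("dup", c("A", "A")), "duplicate")
})
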