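# Fixture builders shared across the test files. Everything is generated in
# code; no stored data files.

write_lines_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

maf_header <- paste(
  "sample_id", "gene", "chromosome", "start", "ref_allele", "alt_allele",
  "variant_classification",
  sep = "\t"
)

maf_row <- function(sample, gene, class, start = 100, ref = "C", alt = "T",
                    chrom = "1") {
  paste(sample, gene, chrom, start, ref, alt, class, sep = "\t")
}

# a cohort with planted per-gene mutated-sample counts: the first k samples
# of the cohort carry one missense mutation in the gene
make_count_cohort <- function(counts, n, label, prefix = label) {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  ann <- tibble::tibble(
    sample_id = ids, cohort = label, purity = 0.7, ploidy = 2,
    wgd = FALSE, histology = "endometrioid", grade = "2",
    tamoxifen_years = NA_real_, msi_flag = FALSE, bmi = NA_real_
  )
  mut <- purrr::imap(counts, function(k, g) {
    if (k == 0) return(empty_mutations())
    tibble::tibble(
      sample_id = ids[seq_len(k)], gene = g, chromosome = "1",
      start = 1000L + seq_len(k), ref_allele = "C", alt_allele = "T",
      variant_classification = "Missense_Mutation",
      protein_change = NA_character_, protein_position = NA_integer_,
      trinucleotide_context = NA_character_, ccf = NA_real_,
      multiplicity = NA_integer_
    )
  }) |> dplyr::bind_rows()
  cohort(ann, mut)
}

# a cohort in which sample i carries clonal mutations in exactly counts[i]
# distinct driver genes (for early-event comparisons)
make_ccf_cohort <- function(counts, label, driver_genes, prefix = label) {
  ids <- sprintf("%s%03d", prefix, seq_along(counts))
  ann <- tibble::tibble(
    sample_id = ids, cohort = label, purity = 0.7, ploidy = 2,
    wgd = FALSE, histology = "endometrioid", grade = "2",
    tamoxifen_years = NA_real_, msi_flag = FALSE, bmi = NA_real_
  )
  mut <- purrr::imap(counts, function(k, i) {
    if (k == 0) return(empty_mutations())
    tibble::tibble(
      sample_id = ids[i], gene = driver_genes[seq_len(k)], chromosome = "1",
      start = 1000L + seq_len(k), ref_allele = "C", alt_allele = "T",
      variant_classification = "Missense_Mutation",
      protein_change = NA_character_, protein_position = NA_integer_,
      trinucleotide_context = NA_character_, ccf = 1,
      multiplicity = 1L
    )
  }) |> dplyr::bind_rows()
  cohort(ann, mut)
}

# small, fast generator settings for tests that loop over seeds
tiny_sim_config <- function(seed, n_exposed = 25, n_control = 25,
                            gene_probs = NULL,
                            passenger_mutations = c(POLE = 30, MSI = 20,
                                                    CIN = 5, GS = 5),
                            ...) {
  gene_probs <- gene_probs %||% tibble::tibble(
    gene = c("PIK3CA", "PTEN", "TP53"),
    p_exposed = c(0.14, 0.5, 0.3),
    p_control = c(0.48, 0.5, 0.3)
  )
  sim_config(
    n_exposed = n_exposed, n_control = n_control,
    gene_probs = gene_probs,
    passenger_mutations = passenger_mutations,
    genome_mb = 200,
    seed = seed,
    ...
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent brute-force Fisher oracle: enumerate every allocation at the
# observed margins with binomial-coefficient point probabilities
oracle_fisher_probs <- function(n1, n2, m) {
  a <- max(0, m - n2):min(m, n1)
  list(
    a = a,
    probs = choose(m, a) * choose(n1 + n2 - m, n1 - a) / choose(n1 + n2, n1)
  )
}

oracle_fisher_p <- function(tab, sidedness = "two_sided") {
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ]); m <- sum(tab[, 1])
  h <- oracle_fisher_probs(n1, n2, m)
  obs <- tab[1, 1]
  p0 <- h$probs[match(obs, h$a)]
  switch(sidedness,
    two_sided = sum(h$probs[h$probs <= p0 * (1 + 1e-7)]),
    less = sum(h$probs[h$a <= obs]),
    greater = sum(h$probs[h$a >= obs])
  )
}

# exhaustive exact two-sided p for a 2 x c table by full enumeration
oracle_rxc_exact <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  stopifnot(nrow(tab) == 2)
  logp <- function(x) {
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
      lgamma(sum(tab) + 1) - sum(lgamma(x + 1))
  }
  cells <- expand.grid(lapply(cs[-length(cs)], function(cmax) 0:min(cmax, rs[1])))
  total <- 0; obs <- exp(logp(tab))
  for (i in seq_len(nrow(cells))) {
    top <- as.numeric(cells[i, ])
    last <- rs[1] - sum(top)
    if (last < 0 || last > cs[length(cs)]) next
    x <- rbind(c(top, last), cs - c(top, last))
    if (any(x < 0)) next
    p <- exp(logp(x))
    if (p <= obs * (1 + 1e-7)) total <- total + p
  }
  total
}
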