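test_that("alignment simulation honors dimensions, seed, and class mix", {
  spec <- simulation_spec(n_codons = 300, seed = 42)
  sim <- simulate_codon_alignment(spec)
  expect_equal(dim(sim$alignment$codons), c(6L, 300L))
  expect_setequal(rownames(sim$alignment$codons), six_taxa)

  sim2 <- simulate_codon_alignment(spec)
  expect_identical(sim$alignment$codons, sim2$alignment$codons)
  expect_identical(sim$site_class, sim2$site_class)

  # class fractions converge to (p0, p1, p2a, p2b) within 3 binomial SE
  spec_big <- simulation_spec(n_codons = 3000, p0 = 0.6, p1 = 0.3, seed = 9)
  simb <- simulate_codon_alignment(spec_big)
  cls <- branch_site_classes(0.6, 0.3, spec_big$omega0, spec_big$omega2)
  obs <- table(factor(simb$site_class, levels = c("0", "1", "2a", "2b")))
  for (k in 1:4) {
    se <- sqrt(cls$props[k] * (1 - cls$props[k]) / 3000)
    expect_lt(abs(obs[k] / 3000 - cls$props[k]), 3 * se + 1e-9)
  }

  expect_error(simulation_spec(p0 = 0.8, p1 = 0.3), "proportions")
  expect_error(simulation_spec(omega0 = 1.2), "omega0")
})

test_that("pure class-0 simulation yields dN/dS near omega0 (counting oracle)", {
  # kappa = 1 so the unweighted nucleotide-counting estimator is unbiased
  spec <- simulation_spec(n_codons = 4000, kappa = 1, p0 = 1 - 1e-9,
                          p1 = 1e-9, omega0 = 0.25, omega2 = 1, seed = 77)
  sim <- simulate_codon_alignment(spec)
  a <- sim$alignment$codons["hsap", ]
  b <- sim$alignment$codons["ptro", ]
  # per-site expected syn/nonsyn opportunity and observed differences,
  # counting single-nucleotide codon pairs only (short branches)
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  syn_sites <- function(cd) {
    ch <- strsplit(cd, "")[[1]]
    s <- 0
    for (p in 1:3) for (n in setdiff(nts, ch[p])) {
      mut <- ch; mut[p] <- n
      mcd <- paste0(mut, collapse = "")
      if (gc[[mcd]] == "*") next
      if (gc[[mcd]] == gc[[cd]]) s <- s + 1 / 3
    }
    s
  }
  S <- sum(vapply(a, syn_sites, numeric(1)))
  N <- 3 * length(a) - S
  diffs <- which(a != b)
  sd <- nd <- 0
  for (i in diffs) {
    ca <- strsplit(a[i], "")[[1]]; cb <- strsplit(b[i], "")[[1]]
    if (sum(ca != cb) != 1L) next
    if (gc[[a[i]]] == gc[[b[i]]]) sd <- sd + 1 else nd <- nd + 1
  }
  omega_hat <- (nd / N) / (sd / S)
  expect_gt(omega_hat, 0.25 * 0.6)
  expect_lt(omega_hat, 0.25 * 1.6)
})

test_that("gap injection gaps exactly the requested cells", {
  sim <- simulate_codon_alignment(simulation_spec(n_codons = 30, seed = 1))
  aln <- sim$alignment
  expect_identical(inject_gaps(aln, data.frame(taxon = character(),
                                               aa_column = integer(),
                                               run_length = integer())),
                   aln)
  g1 <- inject_gaps(aln, data.frame(taxon = "ggor", aa_column = 13L,
                                    run_length = 1L))
  expect_equal(sum(gap_mask(g1)) - sum(gap_mask(aln)), 1L)
  expect_true(gap_mask(g1)["ggor", 13])
  # overlapping runs gap the union, no double count
  g2 <- inject_gaps(aln, data.frame(taxon = c("ggor", "ggor"),
                                    aa_column = c(5L, 7L),
                                    run_length = c(4L, 4L)))
  expect_equal(sum(gap_mask(g2)["ggor", ]), 6L)
  expect_error(inject_gaps(aln, data.frame(taxon = "ggor", aa_column = 29L,
                                           run_length = 5L)), "range")
})

test_that("column scores hit the requested low fraction", {
  sim <- simulate_codon_alignment(simulation_spec(n_codons = 100, seed = 2))
  expect_true(all(simulate_column_scores(sim$alignment, 0, 1)$score == 1))
  expect_true(all(simulate_column_scores(sim$alignment, 1, 1)$score < 1))
  sc <- simulate_column_scores(sim$alignment, 0.2, seed = 31)
  n_low <- sum(sc$score < 1)
  # binomial 99% interval around 20 of 100
  expect_gt(n_low, stats::qbinom(0.005, 100, 0.2) - 1)
  expect_lt(n_low, stats::qbinom(0.995, 100, 0.2) + 1)
})

test_that("variant simulation round-trips through the fixation caller", {
  gm <- list(gff = toy_gff(len = 90L), gene_id = "gX")
  sites <- c(2L, 5L, 9L, 14L, 20L, 28L)
  flags <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  for (af in c(TRUE, FALSE)) {
    raw <- simulate_variants(gm, sites, flags, seed = 5, af_available = af)
    vcf <- tempfile(fileext = ".vcf")
    write_variants_vcf(raw, vcf)
    v <- read_population_vcf(vcf)
    cmap <- psgscan:::cds_coordinate_map(gm$gff, gm$gene_id)
    called <- vapply(sites, function(s) {
      span <- list(chrom = cmap$chrom,
                   positions = cmap$positions[(3 * s - 2):(3 * s)])
      is_site_fixed(span, v, af_available = af)$fixed
    }, logical(1))
    expect_identical(called, flags)
  }
  expect_error(simulate_variants(gm, 31L, TRUE), "outside CDS")
  # all-fixed zero-variant mode gives an empty body
  v0 <- simulate_variants(gm, c(1L, 2L), c(TRUE, TRUE), seed = 1,
                          benign_variant_prob = 0)
  expect_equal(nrow(v0), 0L)
  # a not-fixed site always leaves a record inside the codon span
  v1 <- simulate_variants(gm, 4L, FALSE, seed = 2)
  expect_gte(nrow(v1), 1L)
  cmap <- psgscan:::cds_coordinate_map(gm$gff, gm$gene_id)
  expect_true(all(v1$pos %in% cmap$positions[10:12]))
})

test_that("expression simulation produces specific and uniform profiles", {
  genes <- sprintf("g%03d", 1:40)
  mat <- simulate_expression(genes, n_tissues = 13, specific_fraction = 0.5,
                             seed = 3)
  expect_equal(dim(mat), c(40L, 13L))
  expect_true(all(mat >= 0))
  lm <- log_transform(mat)
  taus <- apply(lm, 1, tau)
  expect_gt(sum(taus > 0.8), 10)    # specific genes present
  expect_gt(sum(taus < 0.2), 10)    # uniform genes present
  expect_true(all(taus[taus > 0.8] > 0.8))
})

test_that("the full synthetic dataset is cross-referenced and deterministic", {
  dir1 <- file.path(tempdir(), "synth1")
  unlink(dir1, recursive = TRUE)
  ds <- simulate_ortholog_set(n_genes = 20, psg_fraction = 0.25,
                              out_dir = dir1, n_codons = 60, seed = 17)
  expect_equal(sum(ds$truth$is_psg), 5L)    # rounding rule: nearest, ties up
  expect_equal(nrow(ds$truth), 20L)
  fam <- utils::read.delim(file.path(dir1, "family_map.tsv"))
  # every gene appears exactly once per taxon in the family map
  cnt <- table(fam$gene_id)
  expect_true(all(cnt == 6L))
  expect_setequal(names(cnt), ds$truth$gene_id)
  for (g in ds$truth$gene_id) {
    expect_true(file.exists(file.path(dir1, "cds", paste0(g, ".fasta"))))
    expect_true(file.exists(file.path(dir1, "alignments", paste0(g, ".faa"))))
  }
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  # ties-up rounding: 3 genes at 0.5 -> 2 PSGs
  dir2 <- file.path(tempdir(), "synth2")
  unlink(dir2, recursive = TRUE)
  ds2 <- simulate_ortholog_set(n_genes = 3, psg_fraction = 0.5,
                               out_dir = dir2, n_codons = 30, seed = 1)
  expect_equal(sum(ds2$truth$is_psg), 2L)

  # determinism: regenerating with the same seed is byte-identical
  dir3 <- file.path(tempdir(), "synth3")
  unlink(dir3, recursive = TRUE)
  simulate_ortholog_set(n_genes = 3, psg_fraction = 0.5, out_dir = dir3,
                        n_codons = 30, seed = 1)
  for (f in c("cds/g0001.fasta", "alignments/g0002.faa", "truth.tsv",
              "population.vcf", "expression_tpm.tsv")) {
    expect_identical(readLines(file.path(dir3, f)),
                     readLines(file.path(dir2, f)))
  }
})
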