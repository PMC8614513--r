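test_that("back-translation places source codons and gap codons", {
  aln <- backtranslate(c(a = "M-K"), c(a = "ATGAAA"))
  expect_equal(unname(aln$codons["a", ]), c("ATG", "---", "AAA"))

  # gapless alignment is the concatenation of original codons
  cds <- c(a = "ATGAAATTT", b = "ATGAAGTTC")
  prot <- c(a = "MKF", b = "MKF")
  aln <- backtranslate(prot, cds)
  expect_equal(apply(aln$codons, 1, paste0, collapse = ""), cds)

  # terminal stop on the CDS is tolerated
  aln <- backtranslate(c(a = "MK"), c(a = "ATGAAATGA"))
  expect_equal(ncol(aln$codons), 2L)

  # translation mismatch names the taxon
  expect_error(backtranslate(c(bongo = "MM"), c(bongo = "ATGAAA")),
               "bongo")
})

test_that("back-translation round-trips simulated alignments and gap masks", {
  spec <- simulation_spec(n_codons = 40, omega2 = 1, seed = 5)
  sim <- simulate_codon_alignment(spec)
  aln <- inject_gaps(sim$alignment,
                     data.frame(taxon = c("ggor", "nleu"),
                                aa_column = c(5L, 20L),
                                run_length = c(3L, 1L)))
  prot <- apply(translate_alignment(aln), 1, paste0, collapse = "")
  cds <- vapply(alignment_taxa(aln), function(tx)
    paste0(aln$codons[tx, aln$codons[tx, ] != "---"], collapse = ""),
    character(1))
  back <- backtranslate(prot, cds)
  expect_identical(back$codons, aln$codons)
  expect_identical(gap_mask(back), gap_mask(aln))
})

test_that("column scores attach with full coverage and range checks", {
  aln <- mk_aln(a = "ATG AAA TTT", b = "ATG AAG TTC")
  tab <- data.frame(column_index = 1:3, score = c(1, 1, 1))
  expect_equal(attach_column_scores(aln, tab)$scores, c(1, 1, 1))
  expect_error(attach_column_scores(aln, transform(tab, score = c(1, 1.2, 1))),
               "\\[0, 1\\]")
  expect_error(attach_column_scores(aln, tab[1:2, ]), "every alignment column")
  expect_error(attach_column_scores(aln, rbind(tab, tab[1, ])),
               "every alignment column")

  sim <- simulate_codon_alignment(simulation_spec(n_codons = 30, seed = 2))
  sc <- simulate_column_scores(sim$alignment, 0.3, seed = 9)
  aln2 <- attach_column_scores(sim$alignment, sc)
  expect_equal(aln2$scores, sc$score)
})

test_that("site mapping reports per-taxon ungapped and genomic coordinates", {
  aln <- mk_aln(a = "ATG --- AAA TTT", b = "ATG CCC AAA TTT")
  expect_equal(map_site(aln, 1, "a")$ungapped_pos, 1L)
  expect_equal(map_site(aln, 3, "a")$ungapped_pos, 2L)
  expect_equal(map_site(aln, 3, "b")$ungapped_pos, 3L)
  # gapped cell yields NA coordinates, not an error
  ms <- map_site(aln, 2, "a", gff = toy_gff(), gene_id = "gX")
  expect_true(is.na(ms$ungapped_pos))
  expect_true(all(is.na(ms$genomic_pos)))
  expect_error(map_site(aln, 9, "a"), "out of range")

  # forward strand, CDS start 101: aa position 2 -> 104..106
  ms <- map_site(aln, 3, "a", gff = toy_gff(), gene_id = "gX")
  expect_equal(ms$genomic_pos, 104:106)
  expect_equal(ms$strand, "+")

  # reverse strand: first codon is the last three bases, ascending order kept
  msr <- map_site(aln, 1, "b", gff = toy_gff(strand = "-", len = 12L),
                  gene_id = "gX")
  expect_equal(msr$genomic_pos, 110:112)
  expect_equal(msr$strand, "-")

  # codon split across an intron lists its three genomic positions
  ms2 <- map_site(aln, 3, "b", gff = toy_gff_2exon(), gene_id = "gX")
  expect_equal(ms2$genomic_pos, c(107, 108, 109))
  ms3 <- map_site(aln, 4, "b", gff = toy_gff_2exon(), gene_id = "gX")
  expect_equal(ms3$genomic_pos, c(110, 201, 202))
})

test_that("non-gap coordinate mapping is a bijection per taxon", {
  spec <- simulation_spec(n_codons = 25, seed = 8)
  aln <- inject_gaps(simulate_codon_alignment(spec)$alignment,
                     data.frame(taxon = "hsap", aa_column = 4L,
                                run_length = 6L))
  pos <- vapply(seq_len(25), function(cc)
    map_site(aln, cc, "hsap")$ungapped_pos, integer(1))
  seen <- pos[!is.na(pos)]
  expect_equal(seen, seq_along(seen))      # strictly increasing, no repeats
  expect_equal(sum(is.na(pos)), 6L)
})

test_that("codon alignment FASTA round-trips", {
  sim <- simulate_codon_alignment(simulation_spec(n_codons = 12, seed = 3))
  aln <- inject_gaps(sim$alignment, data.frame(taxon = "mmul", aa_column = 2L,
                                               run_length = 2L))
  path <- tempfile(fileext = ".fasta")
  write_codon_alignment(aln, path)
  back <- read_codon_alignment(path)
  expect_identical(back$codons, aln$codons)
})

test_that("invalid codons are rejected at construction", {
  expect_error(mk_aln(a = "ATG TAA"), "invalid codon")   # stop codon
  expect_error(mk_aln(a = "AT- AAA"), "invalid codon")
  expect_silent(mk_aln(a = "ATG ANN"))                   # masked is fine
})
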