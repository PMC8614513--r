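test_that("candidate calls require significance and a selected site", {
  expect_true(candidate_from_fit(0.01, c(3L, 7L)))
  expect_false(candidate_from_fit(0.01, integer(0)))
  expect_false(candidate_from_fit(0.05, c(3L)))   # strict inequality
  expect_false(candidate_from_fit(NA, c(3L)))     # unconverged
})

test_that("gap proximity uses an inclusive +/- 5 residue window", {
  sim <- simulate_codon_alignment(simulation_spec(n_codons = 40, seed = 6))
  base <- sim$alignment
  gap_at <- function(col) inject_gaps(base, data.frame(
    taxon = "nleu", aa_column = col, run_length = 1L))
  expect_false(gap_proximity_filter(10L, gap_at(13L))$pass)  # distance 3
  expect_true(gap_proximity_filter(10L, gap_at(16L))$pass)   # distance 6
  expect_false(gap_proximity_filter(10L, gap_at(15L))$pass)  # distance 5, in
  expect_false(gap_proximity_filter(10L, gap_at(10L))$pass)  # own column
  # mode "all": gene survives while one selected site is clean
  r <- gap_proximity_filter(c(10L, 30L), gap_at(13L), mode = "all")
  expect_true(r$pass)
  expect_equal(r$failing_sites, 10L)
  # gaps in any taxon count, not only the foreground species
  g2 <- inject_gaps(base, data.frame(taxon = "mmul", aa_column = 12L,
                                     run_length = 1L))
  expect_false(gap_proximity_filter(10L, g2)$pass)
})

test_that("column-score filter fails on any sub-threshold selected site", {
  scores <- rep(1, 20); scores[7] <- 0.98
  expect_true(column_score_filter(c(3L, 12L), scores)$pass)
  expect_false(column_score_filter(c(3L, 7L), scores)$pass)
  expect_true(column_score_filter(c(3L, 7L), scores, threshold = 0.9)$pass)
  expect_error(column_score_filter(5L, NULL), "no column scores")
})

test_that("relaxation filter drops only significant relaxation", {
  expect_false(relaxation_filter(0.5, 0.01))
  expect_true(relaxation_filter(0.5, 0.2))
  expect_true(relaxation_filter(1.3, 0.001))
  expect_warning(ok <- relaxation_filter(0.5, 0.01, converged = FALSE),
                 "unconverged")
  expect_true(ok)
})

test_that("the cascade reproduces a planted design exactly", {
  pl <- planted_cascade()
  res <- run_cascade(pl$fits, pl$beb, pl$alignments, pl$relax)
  for (br in c("hsap", "ggor")) {
    sc <- res$stage_counts[res$stage_counts$branch == br, ]
    expect_equal(sc$n_candidates, 4L)
    expect_equal(sc$n_after_gap_filter, 3L)
    expect_equal(sc$n_after_column_filter, 2L)
    expect_equal(sc$n_after_relax_filter, 1L)
    expect_equal(res$records$gene[res$records$psg &
                                    res$records$branch == br], "gA")
  }
  # monotone non-increase across stages
  sc <- res$stage_counts
  expect_true(all(sc$n_candidates >= sc$n_after_gap_filter))
  expect_true(all(sc$n_after_gap_filter >= sc$n_after_column_filter))
  expect_true(all(sc$n_after_column_filter >= sc$n_after_relax_filter))
})

test_that("cascade verdicts are order-independent and filters can be disabled", {
  pl <- planted_cascade()
  res <- run_cascade(pl$fits, pl$beb, pl$alignments, pl$relax)
  perm <- sample(nrow(pl$fits))
  res2 <- run_cascade(pl$fits[perm, ], pl$beb, pl$alignments, pl$relax)
  key <- function(d) d[order(d$gene, d$branch),
                       c("gene", "branch", "candidate", "psg")]
  expect_equal(key(res$records), key(res2$records), ignore_attr = TRUE)

  # all filters off: final set equals the candidate set
  res3 <- run_cascade(pl$fits, pl$beb, pl$alignments, pl$relax,
                      enabled = c(gap = FALSE, score = FALSE, relax = FALSE))
  expect_equal(res3$records$psg, res3$records$candidate)

  # no candidates at all: zero counts everywhere
  f0 <- pl$fits; f0$p <- 0.9
  res4 <- run_cascade(f0, pl$beb, pl$alignments, pl$relax)
  expect_true(all(res4$stage_counts$n_candidates == 0))
  expect_true(all(res4$stage_counts$n_after_relax_filter == 0))
})
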