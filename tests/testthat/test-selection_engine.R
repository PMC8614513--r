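# Rate-matrix construction, transition probabilities, pruning likelihood,
# and the model fits.

test_that("rate matrix matches an independently coded entry-by-entry oracle", {
  kappa <- 2; omega <- 0.5
  set.seed(1)
  pi <- as.vector(stats::runif(61, 0.5, 1.5)); pi <- pi / sum(pi)
  Q <- codon_rate_matrix(kappa, omega, pi, scale = FALSE)

  # oracle: direct construction from the genetic code, no shared tables
  codons <- names(Biostrings::GENETIC_CODE)
  codons <- codons[Biostrings::GENETIC_CODE != "*"]
  # package order differs; align by name
  codons <- rownames(Q)
  oracle_entry <- function(ci, cj) {
    a <- strsplit(ci, "")[[1]]; b <- strsplit(cj, "")[[1]]
    d <- which(a != b)
    if (length(d) != 1L) return(0)
    ts <- paste0(sort(c(a[d], b[d])), collapse = "") %in% c("AG", "CT")
    syn <- Biostrings::GENETIC_CODE[[ci]] == Biostrings::GENETIC_CODE[[cj]]
    (if (ts) kappa else 1) * (if (syn) 1 else omega) * pi[match(cj, codons)]
  }
  idx <- cbind(sample(61, 80, TRUE), sample(61, 80, TRUE))
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    expect_equal(Q[i, j], oracle_entry(codons[i], codons[j]), tolerance = 1e-12)
  }
  # synonymous transition vs nonsynonymous transversion rate ratio
  expect_equal(Q["AAA", "AAG"] / Q["AAA", "AAT"],
               kappa / omega * pi[match("AAG", codons)] /
                 pi[match("AAT", codons)])

  expect_lt(max(abs(rowSums(Q))), 1e-10)
  piu <- uniform_codon_frequencies()
  Qu <- codon_rate_matrix(2, 1, piu, scale = FALSE)
  expect_lt(max(abs(piu * Qu - t(piu * t(Qu)))), 1e-14)  # reversibility
  Qs <- codon_rate_matrix(3, 0.2, pi)
  expect_equal(-sum(pi * diag(Qs)), 1, tolerance = 1e-12)
})

test_that("transition probabilities satisfy the semigroup properties", {
  pi <- uniform_codon_frequencies()
  expect_equal(codon_pmatrix(2, 0.5, 0), diag(61), ignore_attr = TRUE,
               tolerance = 1e-12)
  P <- codon_pmatrix(2, 0.5, 0.4, pi)
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, 61), tolerance = 1e-10)
  Pinf <- codon_pmatrix(2, 0.5, 10000, pi)
  expect_lt(max(abs(sweep(Pinf, 2, pi))), 1e-6)          # stationarity
  P1 <- codon_pmatrix(2, 0.5, 0.15, pi)
  P2 <- codon_pmatrix(2, 0.5, 0.35, pi)
  expect_lt(max(abs(P1 %*% P2 - codon_pmatrix(2, 0.5, 0.5, pi))), 1e-8)
  expect_error(codon_pmatrix(2, 0.5, -1), ">= 0")
})

test_that("pruning equals exhaustive internal-state enumeration", {
  # 3 taxa, 3 codons, one internal node: sum over its 61 states
  tr <- ape::read.tree(text = "(a:0.2,b:0.35,c:0.15);")
  lt <- labeled_tree(tr, "a")
  pi <- uniform_codon_frequencies()
  kappa <- 2.3
  cls <- branch_site_classes(0.5, 0.3, 0.2, 4)
  tab_codons <- sense_codons()
  set.seed(11)
  cd <- matrix(tab_codons[sample(61, 9, TRUE)], nrow = 3,
               dimnames = list(c("a", "b", "c"), NULL))
  cd[2, 2] <- "---"
  aln <- codon_alignment(cd)
  ll <- site_log_likelihood(aln, lt, kappa, cls, pi)

  states <- match(cd, tab_codons)
  dim(states) <- dim(cd)
  brute_class <- function(s, om_fg, om_bg) {
    Pa <- codon_pmatrix(kappa, om_fg, 0.2 / ll$rho, pi, scale = FALSE)
    Pb <- codon_pmatrix(kappa, om_bg, 0.35 / ll$rho, pi, scale = FALSE)
    Pc <- codon_pmatrix(kappa, om_bg, 0.15 / ll$rho, pi, scale = FALSE)
    tot <- 0
    for (r in 1:61) {
      term <- pi[r]
      term <- term * (if (is.na(states[1, s])) 1 else Pa[r, states[1, s]])
      term <- term * (if (is.na(states[2, s])) 1 else Pb[r, states[2, s]])
      term <- term * (if (is.na(states[3, s])) 1 else Pc[r, states[3, s]])
      tot <- tot + term
    }
    tot
  }
  for (s in 1:3) {
    mix <- sum(vapply(seq_along(cls$props), function(k)
      cls$props[k] * brute_class(s, cls$omega_fg[k], cls$omega_bg[k]),
      numeric(1)))
    expect_equal(ll$per_site[s], log(mix), tolerance = 1e-8)
  }
})

test_that("degenerate cases of the site likelihood behave", {
  # identical sequences, t = 0 everywhere, single class:
  # total = sum over sites of log pi(observed codon)
  tr <- ape::read.tree(text = "(a:0,b:0,c:0);")
  lt <- labeled_tree(tr, "a")
  set.seed(3)
  pi <- as.vector(stats::runif(61)); pi <- pi / sum(pi)
  cd <- matrix(rep(sense_codons()[c(5, 17, 40)], each = 3), nrow = 3)
  rownames(cd) <- c("a", "b", "c")
  aln <- codon_alignment(cd)
  ll <- site_log_likelihood(aln, lt, 2, m0_classes(0.5), pi)
  expect_equal(ll$total, sum(log(pi[c(5, 17, 40)])), tolerance = 1e-10)

  # p0 = 1 branch-site mixture collapses to M0 at omega0
  spec <- simulation_spec(n_codons = 20, seed = 4)
  sim <- simulate_codon_alignment(spec)
  piu <- uniform_codon_frequencies()
  bs <- site_log_likelihood(sim$alignment, spec$tree, 2,
                            branch_site_classes(1 - 1e-12, 1e-12, 0.3, 1), piu)
  m0 <- site_log_likelihood(sim$alignment, spec$tree, 2, m0_classes(0.3), piu)
  # scaling differs between the two class specs; compare at matched scale
  expect_equal(bs$per_site, m0$per_site, tolerance = 1e-3)

  # an all-gap column contributes log(1) = 0 and is flagged
  aln2 <- inject_gaps(sim$alignment,
                      data.frame(taxon = six_taxa, aa_column = 7L,
                                 run_length = 1L))
  ll2 <- site_log_likelihood(aln2, spec$tree, 2, m0_classes(0.3), piu)
  expect_equal(ll2$all_gap_columns, 7L)
  expect_equal(ll2$per_site[7], 0)
})

test_that("likelihood is invariant to taxon order and root placement", {
  spec <- simulation_spec(n_codons = 30, seed = 12)
  sim <- simulate_codon_alignment(spec)
  pi <- uniform_codon_frequencies()
  cls <- branch_site_classes(0.6, 0.3, 0.2, 3)
  base <- site_log_likelihood(sim$alignment, spec$tree, 2.5, cls, pi)$total

  perm <- sim$alignment
  perm$codons <- perm$codons[rev(rownames(perm$codons)), ]
  expect_equal(site_log_likelihood(perm, spec$tree, 2.5, cls, pi)$total,
               base, tolerance = 1e-8)

  # re-rooted representation of the same unrooted topology, foreground kept
  # (trifurcation moved to the great-ape stem node; same edges and lengths)
  tr2 <- ape::read.tree(text = paste0(
    "(((hsap:0.25,ptro:0.25)Hominini:0.08,ggor:0.18)Homininae:0.08,",
    "pabe:0.25,(nleu:0.35,mmul:0.45)Out:0.12);"))
  lt2 <- labeled_tree(tr2, "hsap")
  expect_equal(site_log_likelihood(sim$alignment, lt2, 2.5, cls, pi)$total,
               base, tolerance = 1e-6)
})

test_that("M0 recovers omega and degenerates sensibly", {
  spec <- simulation_spec(n_codons = 500, p0 = 1 - 1e-9, p1 = 1e-9,
                          omega0 = 0.3, omega2 = 1, seed = 21)
  sim <- simulate_codon_alignment(spec)
  m0 <- fit_m0(sim$alignment, great_ape_tree())
  expect_true(m0$converged)
  expect_gt(m0$omega, 0.2)
  expect_lt(m0$omega, 0.45)

  # identical sequences: branch lengths collapse to ~0
  cd <- matrix(rep(sense_codons()[sample(61, 30, replace = TRUE)], each = 6),
               nrow = 6)
  rownames(cd) <- six_taxa
  m0c <- fit_m0(codon_alignment(cd), great_ape_tree())
  expect_lt(sum(m0c$tree$edge.length), 1e-3)
})

test_that("branch-site alternative nests the null and the null pins omega2", {
  tree <- great_ape_tree()
  lt <- labeled_tree(tree, "hsap")
  for (seed in c(31, 32)) {
    sim <- simulate_codon_alignment(
      simulation_spec(n_codons = 150, omega2 = 1, seed = seed))
    m0 <- fit_m0(sim$alignment, tree)
    ts <- branch_site_test(sim$alignment, lt, m0)
    alt <- ts$alt; nul <- ts$null
    expect_gte(alt$loglik, nul$loglik - 1e-6)
    expect_identical(nul$omega2, 1)
    expect_true(alt$omega2 >= 1 && alt$omega2 <= 999)
    p <- alt[c("p0", "p1", "p2a", "p2b")]
    expect_equal(sum(unlist(p)), 1, tolerance = 1e-9)
  }
})

test_that("the likelihood-ratio test handles boundaries", {
  expect_equal(lrt(-100, -100)$p, 1)
  expect_equal(lrt(-100 + 3.841459 / 2, -100)$p, 0.05, tolerance = 1e-4)
  j <- lrt(-100.000001, -100)     # numerical jitter: alt slightly below null
  expect_equal(j$statistic, 0)
  expect_equal(j$p, 1)
  expect_error(lrt(NA, -100))
})

test_that("relax-style fit is nested and flags relaxation direction", {
  tree <- great_ape_tree()
  lt <- labeled_tree(tree, "hsap")
  cls <- relax_classes(0.45, 0.45, 0.1, 4, 0.2)   # strong relaxation
  sim <- psgscan:::simulate_classes_alignment(
    lt, 250, 2.5, cls, uniform_codon_frequencies(), 801)
  m0 <- fit_m0(sim$alignment, tree)
  rf <- fit_relax_style(sim$alignment, lt, m0)
  expect_true(rf$converged)
  expect_gte(rf$loglik_alt, rf$loglik_null - 1e-6)
  expect_gt(rf$K, 0)
  expect_lt(rf$K, 1)              # strong relaxation detected
})

test_that("BEB posteriors cover all columns and separate planted sites", {
  tree <- great_ape_tree()
  lt <- labeled_tree(tree, "hsap")
  sim <- simulate_codon_alignment(
    simulation_spec(n_codons = 200, omega2 = 10, seed = 604))
  m0 <- fit_m0(sim$alignment, tree)
  alt <- fit_branch_site(sim$alignment, lt, m0)
  bb <- beb_site_posteriors(sim$alignment, lt, m0, alt)
  expect_length(bb$posterior, 200L)
  expect_true(all(bb$posterior >= 0 & bb$posterior <= 1))
  sel <- sim$site_class %in% c("2a", "2b")
  expect_gt(mean(bb$posterior[sel]), mean(bb$posterior[!sel]))
})
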