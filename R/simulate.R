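# Synthetic-data generators. Every input the scan consumes can be produced
# here with the statistical structure the analysis assumes: codon alignments
# evolved under the branch-site process on the six-taxon tree, gap patterns,
# alignment column scores, population variant tables, tissue expression
# profiles, and gene-family maps. All randomness flows from one integer seed
# through named sub-streams, so each stage is reproducible on its own.

# Deterministic sub-seed per named stage, kept below 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  ((abs(seed) %% 1000003) * 2039 + h) %% 2147483647
}

#' Simulation settings for one codon alignment
#'
#' Bundles the branch-site generative parameters: site-class proportions
#' (p0 conserved, p1 neutral; p2a/p2b derived), omega0 in (0,1), omega2 >= 1
#' applied on the foreground branch, kappa, codon frequencies, and the tree.
#'
#' @param tree A [labeled_tree()]; default [great_ape_tree()] with foreground
#'   `"hsap"`.
#' @param n_codons Number of codon sites.
#' @param kappa Transition/transversion ratio.
#' @param p0,p1 Site-class proportions, `p0 + p1 <= 1`.
#' @param omega0 Conserved-class omega in (0,1).
#' @param omega2 Foreground selected-class omega (1 = null model).
#' @param codon_freqs 61-vector of codon frequencies summing to 1.
#' @param seed Integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(tree = labeled_tree(great_ape_tree(), "hsap"),
                            n_codons = 300, kappa = 2.5,
                            p0 = 0.7, p1 = 0.2,
                            omega0 = 0.1, omega2 = 8,
                            codon_freqs = uniform_codon_frequencies(),
                            seed = 1) {
  stopifnot(n_codons >= 1, kappa > 0)
  check_branch_site_params(p0, p1, omega0, max(omega2, 1))
  if (omega2 < 1) stop("omega2 must be >= 1")
  if (any(codon_freqs < 0) || abs(sum(codon_freqs) - 1) > 1e-12)
    stop("codon_freqs must be nonnegative and sum to 1")
  stopifnot(inherits(tree, "labeled_tree"),
            length(tree$tree$tip.label) >= 2)
  structure(list(tree = tree, n_codons = as.integer(n_codons), kappa = kappa,
                 p0 = p0, p1 = p1, omega0 = omega0, omega2 = omega2,
                 codon_freqs = codon_freqs, seed = as.integer(seed)),
            class = "simulation_spec")
}

# generic mixture simulator: classes as in likelihood.R class specs
simulate_classes_alignment <- function(ltree, n_codons, kappa, classes, pi,
                                       seed) {
  set.seed(seed)
  ed <- tree_edge_data(ltree)
  tab <- codon_tables()
  nclass <- length(classes$props)
  site_class <- sample.int(nclass, n_codons, replace = TRUE,
                           prob = classes$props)
  rho <- sum(classes$props *
               vapply(classes$omega_bg, function(w) codon_rate(kappa, w, pi),
                      numeric(1)))
  node_states <- matrix(NA_integer_, nrow = ed$nnode, ncol = n_codons)
  root <- ed$parent[length(ed$parent)] + 1L
  node_states[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  # preorder = reversed postorder
  for (e in rev(seq_along(ed$parent))) {
    pa <- ed$parent[e] + 1L; ch <- ed$child[e] + 1L
    t_eff <- ed$blen[e] / rho
    for (k in seq_len(nclass)) {
      idx <- which(site_class == k)
      if (length(idx) == 0L) next
      w <- if (ed$fg[e] == 1L) classes$omega_fg[k] else classes$omega_bg[k]
      P <- cpp_codon_pmatrix(kappa, w, pi, tab$pairs0, t_eff, FALSE)
      for (s in unique(node_states[pa, idx])) {
        ss <- idx[node_states[pa, idx] == s]
        node_states[ch, ss] <- sample.int(61L, length(ss), replace = TRUE,
                                          prob = P[s, ])
      }
    }
  }
  codons <- matrix(tab$codons[node_states[seq_len(ed$ntip), ]],
                   nrow = ed$ntip)
  rownames(codons) <- ed$tip_labels
  list(alignment = codon_alignment(codons), site_class = site_class)
}

#' Simulate a codon alignment under the branch-site process
#'
#' Each site draws a class from (p0, p1, p2a, p2b); codons start from the
#' equilibrium distribution at the root and evolve along every branch with
#' the class- and branch-appropriate omega. Branch lengths are expected
#' substitutions per codon under the background mixture.
#'
#' @param spec A [simulation_spec()].
#' @return List: `alignment` (a [codon_alignment()]), `site_class` (per-site
#'   labels `"0"`, `"1"`, `"2a"`, `"2b"`), `spec`.
#' @export
simulate_codon_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  classes <- branch_site_classes(spec$p0, spec$p1, spec$omega0,
                                 max(spec$omega2, 1))
  sim <- simulate_classes_alignment(
    spec$tree, spec$n_codons, spec$kappa, classes, spec$codon_freqs,
    substream_seed(spec$seed, "alignment"))
  labels <- c("0", "1", "2a", "2b")
  list(alignment = sim$alignment, site_class = labels[sim$site_class],
       spec = spec)
}

#' Inject gap runs into an alignment
#'
#' Replaces the specified amino-acid columns with gap codons in the named
#' taxa; everything else is untouched. Overlapping runs gap the union of
#' their cells.
#'
#' @param aln A [codon_alignment()].
#' @param gap_spec Data frame with columns `taxon`, `aa_column`, `run_length`.
#' @return The modified alignment.
#' @export
inject_gaps <- function(aln, gap_spec) {
  if (nrow(gap_spec) == 0L) return(aln)
  stopifnot(all(c("taxon", "aa_column", "run_length") %in% names(gap_spec)))
  nc <- n_codons(aln)
  for (r in seq_len(nrow(gap_spec))) {
    tx <- gap_spec$taxon[r]
    if (!tx %in% alignment_taxa(aln)) stop("unknown taxon: ", tx)
    from <- gap_spec$aa_column[r]
    len <- gap_spec$run_length[r]
    if (len < 1L) stop("run length must be >= 1")
    to <- from + len - 1L
    if (from < 1L || to > nc) stop("gap run out of alignment range")
    aln$codons[tx, from:to] <- "---"
  }
  aln
}

#' Simulate alignment column confidence scores
#'
#' Approximately `fraction_low` of columns get scores drawn uniformly below
#' 1; the rest score exactly 1.0.
#'
#' @param aln A [codon_alignment()].
#' @param fraction_low Proportion of columns with score < 1.
#' @param seed Integer seed.
#' @return Data frame: `column_index`, `score`.
#' @export
simulate_column_scores <- function(aln, fraction_low, seed = 1) {
  stopifnot(fraction_low >= 0, fraction_low <= 1)
  set.seed(substream_seed(seed, "scores"))
  nc <- n_codons(aln)
  low <- stats::runif(nc) < fraction_low
  score <- rep(1.0, nc)
  score[low] <- stats::runif(sum(low), 0.2, 0.999)
  data.frame(column_index = seq_len(nc), score = score)
}

#' Simulate population variants around selected codons
#'
#' For each amino-acid site flagged fixed, either no variant overlaps its
#' codon or the overlapping variant leaves the assembly allele at frequency
#' > 0.95; each site flagged not-fixed gets at least one violating variant
#' (assembly-allele frequency <= 0.95 when frequencies are simulated, or any
#' segregating alternative allele when they are not).
#'
#' @param gene_model List with `gff` (path or `GRanges`) and `gene_id`, as
#'   consumed by [map_site()]'s coordinate machinery.
#' @param sites Amino-acid positions (in the gene's own CDS coordinates).
#' @param fixed_flags Logical vector aligned with `sites`.
#' @param seed Integer seed.
#' @param af_available Simulate `AF` INFO fields?
#' @param benign_variant_prob Probability that a fixed site carries a
#'   high-frequency-reference variant rather than no variant at all.
#' @return Data frame of VCF-shaped records (`chrom`, `pos`, `id`, `ref`,
#'   `alt`, `qual`, `filter`, `info`); zero rows when nothing segregates.
#' @export
simulate_variants <- function(gene_model, sites, fixed_flags, seed = 1,
                              af_available = TRUE,
                              benign_variant_prob = 0.5) {
  stopifnot(length(sites) == length(fixed_flags))
  set.seed(substream_seed(seed, "variants"))
  cmap <- cds_coordinate_map(gene_model$gff, gene_model$gene_id)
  n_aa <- length(cmap$positions) %/% 3L
  rows <- list()
  nts <- c("A", "C", "G", "T")
  for (i in seq_along(sites)) {
    s <- sites[i]
    if (s < 1L || s > n_aa) stop("site outside CDS: ", s)
    span <- cmap$positions[(3L * s - 2L):(3L * s)]
    pos <- sample(span, 1L)
    ref <- sample(nts, 1L)
    alt <- sample(setdiff(nts, ref), 1L)
    if (fixed_flags[i]) {
      if (!af_available || stats::runif(1) > benign_variant_prob) next
      af <- stats::runif(1, 0.001, 0.049)   # assembly allele keeps > 0.95
    } else {
      af <- if (af_available) stats::runif(1, 0.06, 0.6) else NA_real_
    }
    info <- if (af_available) sprintf("AF=%.4f", af) else "."
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = cmap$chrom, pos = pos, id = ".", ref = ref, alt = alt,
      qual = ".", filter = "PASS", info = info, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), qual = character(),
                      filter = character(), info = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write variant records as VCF v4.2
#'
#' @param variants Data frame from [simulate_variants()].
#' @param path Output path (`.vcf`).
#' @param contigs Optional contig names for the header.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, contigs = NULL) {
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">")
  if (!is.null(contigs))
    meta <- c(meta, sprintf("##contig=<ID=%s>", unique(contigs)))
  header <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  body <- if (nrow(variants)) {
    apply(variants, 1, function(r)
      paste(r[["chrom"]], r[["pos"]], r[["id"]], r[["ref"]], r[["alt"]],
            r[["qual"]], r[["filter"]], r[["info"]], sep = "\t"))
  } else character(0)
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' Simulate a TPM expression matrix
#'
#' About `specific_fraction` of genes are expressed dominantly in one tissue
#' (tissue-specificity tau near 1); the rest are near-uniform (tau near 0).
#'
#' @param genes Character vector of gene ids.
#' @param n_tissues Number of tissues (>= 2).
#' @param specific_fraction Proportion of tissue-specific genes.
#' @param seed Integer seed.
#' @return Numeric matrix genes x tissues of TPM values (raw scale).
#' @export
simulate_expression <- function(genes, n_tissues = 13,
                                specific_fraction = 0.3, seed = 1) {
  stopifnot(n_tissues >= 2)
  set.seed(substream_seed(seed, "expression"))
  n <- length(genes)
  specific <- stats::runif(n) < specific_fraction
  mat <- matrix(0, nrow = n, ncol = n_tissues,
                dimnames = list(genes, paste0("tissue", seq_len(n_tissues))))
  for (i in seq_len(n)) {
    if (specific[i]) {
      dom <- sample.int(n_tissues, 1L)
      mat[i, ] <- stats::runif(n_tissues, 0, 0.4)
      mat[i, dom] <- stats::rlnorm(1, log(200), 0.4)
    } else {
      base <- stats::rlnorm(1, log(50), 0.3)
      mat[i, ] <- base * stats::rlnorm(n_tissues, 0, 0.08)
    }
  }
  mat
}

# truncated geometric family sizes (1-based, capped)
family_sizes <- function(n_genes, p = 0.55, cap = 4L) {
  sizes <- integer(0)
  total <- 0L
  while (total < n_genes) {
    s <- min(1L + stats::rgeom(1, p), cap, n_genes - total)
    sizes <- c(sizes, s)
    total <- total + s
  }
  sizes
}

#' Simulate a complete cross-referenced ortholog dataset
#'
#' Generates everything the end-to-end scan consumes: per-gene CDS FASTA
#' (headers `taxon|gene`), protein alignment FASTA, column-score TSV, a
#' marked newick tree, family map TSV, per-gene GFF3 gene models, a VCF of
#' population variants, an expression TSV, a disease-gene TSV, a truth table
#' TSV, and a JSON manifest. Genes flagged PSG in the truth table are
#' simulated with `omega2 = psg_omega2` on the designated foreground branch;
#' the rest with `omega2 = 1`. The PSG count is `psg_fraction * n_genes`
#' rounded to the nearest integer, ties up.
#'
#' @param n_genes Number of ortholog groups.
#' @param psg_fraction Fraction simulated under positive selection.
#' @param out_dir Output directory (created).
#' @param foreground Foreground branch name for the PSG simulations.
#' @param n_codons Codon columns per gene.
#' @param psg_omega2 Foreground omega2 for PSG genes.
#' @param n_tissues,specific_fraction Passed to [simulate_expression()].
#' @param gap_fraction Fraction of genes receiving one random gap run.
#' @param score_fraction_low Fraction of low-confidence alignment columns.
#' @param disease_fraction Fraction of genes put on the disease list.
#' @param fixed_site_prob Probability a planted selected site is fixed in
#'   the simulated population.
#' @param family_geom_p Truncated-geometric parameter for family sizes.
#' @param seed Integer master seed.
#' @return List: `manifest` (paths), `truth` (data frame), `out_dir`.
#' @export
simulate_ortholog_set <- function(n_genes, psg_fraction, out_dir,
                                  foreground = "hsap",
                                  n_codons = 300, psg_omega2 = 8,
                                  n_tissues = 13, specific_fraction = 0.3,
                                  gap_fraction = 0, score_fraction_low = 0,
                                  disease_fraction = 0.2,
                                  fixed_site_prob = 0.8,
                                  family_geom_p = 0.55,
                                  seed = 1) {
  stopifnot(psg_fraction >= 0, psg_fraction <= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("cds", "alignments", "scores", "models"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  n_psg <- floor(psg_fraction * n_genes + 0.5)   # ties up
  is_psg <- c(rep(TRUE, n_psg), rep(FALSE, n_genes - n_psg))

  tree <- great_ape_tree()
  ltree <- labeled_tree(tree, foreground)
  tree_path <- file.path(out_dir, "species_tree.nwk")
  write_labeled_tree(ltree, tree_path)

  set.seed(substream_seed(seed, "set"))
  gapped_genes <- genes[stats::runif(n_genes) < gap_fraction]

  truth_rows <- list()
  gff_all <- list()
  vcf_all <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    gseed <- substream_seed(seed, paste0("gene_", g))
    spec <- simulation_spec(tree = ltree, n_codons = n_codons,
                            omega2 = if (is_psg[gi]) psg_omega2 else 1,
                            seed = gseed)
    sim <- simulate_codon_alignment(spec)
    aln <- sim$alignment
    if (g %in% gapped_genes) {
      gap_col <- sample.int(n_codons - 5L, 1L)
      aln <- inject_gaps(aln, data.frame(taxon = sample(alignment_taxa(aln), 1),
                                         aa_column = gap_col, run_length = 3L))
    }
    # ungapped CDS per taxon
    cds <- vapply(alignment_taxa(aln), function(tx) {
      paste0(aln$codons[tx, aln$codons[tx, ] != "---"], collapse = "")
    }, character(1))
    names(cds) <- paste0(alignment_taxa(aln), "|", g)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds),
                                file.path(out_dir, "cds", paste0(g, ".fasta")))
    prot <- apply(translate_alignment(aln), 1, paste0, collapse = "")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(prot),
                                file.path(out_dir, "alignments",
                                          paste0(g, ".faa")))
    scores <- simulate_column_scores(aln, score_fraction_low, seed = gseed)
    utils::write.table(scores,
                       file.path(out_dir, "scores", paste0(g, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    # toy single-exon gene model on the focal taxon, one contig per gene
    n_aa_hs <- sum(aln$codons[foreground_tip(ltree), ] != "---")
    cds_len <- 3L * n_aa_hs
    gff_all[[g]] <- data.frame(
      seqid = g, source = "psgscan_sim",
      type = c("gene", "mRNA", "CDS"),
      start = c(101L, 101L, 101L), end = 100L + cds_len,
      score = ".", strand = "+", phase = c(".", ".", "0"),
      attributes = c(sprintf("ID=%s", g),
                     sprintf("ID=%s.t1;Parent=%s", g, g),
                     sprintf("ID=%s.cds;Parent=%s.t1", g, g)),
      stringsAsFactors = FALSE)
    # planted selected sites (class 2a/2b, ungapped in focal taxon)
    sel <- which(sim$site_class %in% c("2a", "2b"))
    fg_row <- aln$codons[foreground_tip(ltree), ]
    sel <- sel[fg_row[sel] != "---"]
    sel_pos <- vapply(sel, function(cc) sum(fg_row[seq_len(cc)] != "---"),
                      integer(1))
    sel_take <- utils::head(sel_pos, 6L)
    flags <- stats::runif(length(sel_take)) < fixed_site_prob
    if (is_psg[gi] && length(sel_take)) {
      gm <- list(gff = gff_df_to_granges(gff_all[[g]]), gene_id = g)
      vcf_all[[g]] <- simulate_variants(gm, sel_take, flags, seed = gseed)
    }
    truth_rows[[gi]] <- data.frame(
      gene_id = g, is_psg = is_psg[gi], fg_branch = foreground,
      sel_sites = paste(sel_take, collapse = ";"),
      fixed_flags = paste(as.integer(flags), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)

  gff_df <- do.call(rbind, gff_all)
  gff_path <- file.path(out_dir, "models", "genes.gff3")
  writeLines(c("##gff-version 3",
               apply(gff_df, 1, paste, collapse = "\t")), gff_path)
  vcf_path <- file.path(out_dir, "population.vcf")
  vcf_df <- if (length(vcf_all)) do.call(rbind, vcf_all) else
    simulate_variants(list(gff = gff_df_to_granges(gff_all[[1]]),
                           gene_id = genes[1]), integer(0), logical(0))
  write_variants_vcf(vcf_df, vcf_path, contigs = genes)

  # family map: truncated-geometric family sizes over ortholog groups; a
  # family with >= 2 groups contributes >= 2 genes per taxon, hence "multi"
  set.seed(substream_seed(seed, "families"))
  sizes <- family_sizes(n_genes, family_geom_p)
  fam_id <- rep(sprintf("fam%04d", seq_along(sizes)), sizes)
  shuffled <- sample(genes)
  taxa6 <- tree$tip.label
  fam_rows <- do.call(rbind, lapply(seq_along(shuffled), function(i) {
    data.frame(gene_id = shuffled[i], family_id = fam_id[i],
               taxon = taxa6, stringsAsFactors = FALSE)
  }))
  fam_path <- file.path(out_dir, "family_map.tsv")
  utils::write.table(fam_rows, fam_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  expr <- simulate_expression(genes, n_tissues, specific_fraction,
                              seed = substream_seed(seed, "expr"))
  expr_path <- file.path(out_dir, "expression_tpm.tsv")
  utils::write.table(data.frame(gene_id = rownames(expr), expr,
                                check.names = FALSE),
                     expr_path, sep = "\t", row.names = FALSE, quote = FALSE)

  set.seed(substream_seed(seed, "disease"))
  disease <- genes[stats::runif(n_genes) < disease_fraction]
  disease_path <- file.path(out_dir, "disease_genes.tsv")
  utils::write.table(data.frame(gene_id = disease), disease_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  manifest <- list(
    n_genes = n_genes, n_psg = n_psg, foreground = foreground,
    n_codons = n_codons, psg_omega2 = psg_omega2, seed = seed,
    paths = list(tree = tree_path, gff = gff_path, vcf = vcf_path,
                 family_map = fam_path, expression = expr_path,
                 disease = disease_path, truth = truth_path,
                 cds_dir = file.path(out_dir, "cds"),
                 alignment_dir = file.path(out_dir, "alignments"),
                 score_dir = file.path(out_dir, "scores")))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  list(manifest = manifest, truth = truth, out_dir = out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tip used for per-species coordinates in generated gene models: the
# foreground tip when terminal, else human
foreground_tip <- function(ltree) {
  if (ltree$foreground %in% ltree$tree$tip.label) ltree$foreground else "hsap"
}

gff_df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    type = df$type,
    ID = sub("ID=([^;]+).*", "\\1", df$attributes))
}
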