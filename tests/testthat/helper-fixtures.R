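# Shared fixtures, built in code.

# small codon alignment from codon strings (one string of codons per taxon)
mk_aln <- function(..., scores = NULL) {
  rows <- list(...)
  codons <- do.call(rbind, lapply(rows, function(s) strsplit(s, " ")[[1]]))
  rownames(codons) <- names(rows)
  codon_alignment(codons, scores = scores)
}

# toy single-exon forward-strand gene model as a GRanges (CDS starts at 101)
toy_gff <- function(gene = "gX", chrom = "chr1", start = 101L, len = 30L,
                    strand = "+") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = start + len - 1L),
    strand = strand,
    type = "CDS",
    ID = paste0(gene, ".cds"))
}

# two-exon gene model: codon 4 spans the junction when exon1 length = 10
toy_gff_2exon <- function(gene = "gX", chrom = "chr1", strand = "+") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = c(101L, 201L), end = c(110L, 220L)),
    strand = strand,
    type = "CDS",
    ID = paste0(gene, ".cds"))
}

six_taxa <- c("hsap", "ptro", "ggor", "pabe", "nleu", "mmul")

# deterministic random CDS (sense codons only, no terminal stop)
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  paste0(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# hand-planted cascade inputs: per branch, one gene lost at each stage
planted_cascade <- function() {
  sim <- simulate_codon_alignment(simulation_spec(n_codons = 60, seed = 20))
  clean <- attach_column_scores(sim$alignment,
                                data.frame(column_index = 1:60, score = 1))
  lowscore <- clean
  lowscore$scores[30] <- 0.9
  gapped <- inject_gaps(clean, data.frame(taxon = "ggor", aa_column = 12L,
                                          run_length = 1L))
  alignments <- list(gA = clean, gB = gapped, gC = lowscore, gD = clean,
                     gE = clean)
  fits <- expand.grid(gene = names(alignments), branch = c("hsap", "ggor"),
                      stringsAsFactors = FALSE)
  fits$p <- 0.01
  fits$p[fits$gene == "gE"] <- 0.5        # never a candidate
  beb <- list()
  for (br in c("hsap", "ggor")) {
    beb[[paste0("gA|", br)]] <- c(20L)    # survives everything
    beb[[paste0("gB|", br)]] <- c(10L)    # gap at 12 kills it
    beb[[paste0("gC|", br)]] <- c(30L)    # low column score kills it
    beb[[paste0("gD|", br)]] <- c(40L)    # relaxation kills it
  }
  relax <- expand.grid(gene = names(alignments), branch = c("hsap", "ggor"),
                       stringsAsFactors = FALSE)
  relax$K <- ifelse(relax$gene == "gD", 0.4, 1.2)
  relax$p <- ifelse(relax$gene == "gD", 0.001, 0.3)
  relax$converged <- TRUE
  list(fits = fits, beb = beb, alignments = alignments, relax = relax)
}
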