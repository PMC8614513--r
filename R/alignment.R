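#' Codon alignment container
#'
#' A codon alignment stores one row of aligned codons per taxon plus an
#' optional per-column confidence score (one score per amino-acid column,
#' in `[0, 1]`). Gap codons are written `"---"`; codons containing `N` are
#' kept but masked (treated as missing data) in all likelihood computations.
#'
#' @param codons Character matrix, rows = taxa (rownames required), columns =
#'   codon sites; entries are sense codons, `"---"`, or N-containing codons.
#' @param scores Optional numeric vector, one score in `[0, 1]` per column.
#' @return A `codon_alignment` object.
#' @export
codon_alignment <- function(codons, scores = NULL) {
  stopifnot(is.matrix(codons), !is.null(rownames(codons)))
  tab <- codon_tables()
  flat <- as.vector(codons)
  ok <- flat == "---" | flat %in% tab$codons |
    (nchar(flat) == 3L & grepl("N", flat) & grepl("^[ACGTN]{3}$", flat))
  if (!all(ok)) {
    bad <- unique(flat[!ok])
    stop("invalid codon(s) in alignment: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(scores)) {
    if (length(scores) != ncol(codons)) stop("one score per column required")
    if (any(scores < 0 | scores > 1)) stop("column scores must lie in [0, 1]")
  }
  structure(list(codons = codons, scores = scores), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", nrow(x$codons), "taxa x", ncol(x$codons),
      "codon columns;", if (is.null(x$scores)) "no" else "with",
      "column scores\n")
  invisible(x)
}

#' Number of codon columns
#' @param aln A [codon_alignment()].
#' @return Integer column count.
#' @export
n_codons <- function(aln) ncol(aln$codons)

#' Alignment taxa
#' @param aln A [codon_alignment()].
#' @return Character vector of taxon names.
#' @export
alignment_taxa <- function(aln) rownames(aln$codons)

#' Gap mask of an alignment
#'
#' @param aln A [codon_alignment()].
#' @return Logical matrix, `TRUE` where a taxon has a gap codon.
#' @export
gap_mask <- function(aln) {
  aln$codons == "---"
}

# Integer codon states for the likelihood core: 0-based sense-codon index,
# NA for gaps and N-masked codons.
alignment_states <- function(aln) {
  idx <- codon_index(aln$codons)
  m <- matrix(as.integer(idx - 1L), nrow = nrow(aln$codons),
              dimnames = dimnames(aln$codons))
  m
}

#' Write / read a codon alignment as FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path FASTA file path.
#' @return `read_codon_alignment` returns a [codon_alignment()];
#'   `write_codon_alignment` returns `path` invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- apply(aln$codons, 1, paste0, collapse = "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_codon_alignment
#' @export
read_codon_alignment <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  w <- unique(Biostrings::width(seqs))
  if (length(w) != 1L) stop("alignment rows differ in length")
  if (w %% 3L != 0L) stop("alignment length is not a multiple of three")
  chars <- as.character(seqs)
  codons <- t(vapply(chars, function(s) {
    substring(s, seq(1, w, 3), seq(3, w, 3))
  }, character(w / 3)))
  rownames(codons) <- names(seqs)
  codon_alignment(codons)
}

#' Translate an aligned codon matrix to an aligned protein matrix
#'
#' Gap codons become `"-"`, N-containing codons `"X"`.
#'
#' @param aln A [codon_alignment()].
#' @return Character matrix of single-letter amino acids.
#' @export
translate_alignment <- function(aln) {
  tab <- codon_tables()
  flat <- as.vector(aln$codons)
  aa <- rep("X", length(flat))
  aa[flat == "---"] <- "-"
  hit <- match(flat, tab$codons)
  aa[!is.na(hit)] <- tab$aa[hit[!is.na(hit)]]
  matrix(aa, nrow = nrow(aln$codons), dimnames = dimnames(aln$codons))
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Replaces every aligned amino-acid residue by its source codon from the
#' unaligned CDS and every alignment gap by `"---"`. The ungapped protein row
#' must equal the translation of its CDS (a terminal stop codon on the CDS is
#' tolerated and dropped).
#'
#' @param protein_alignment Named character vector (or `AAStringSet`) of
#'   equal-length aligned protein sequences, gaps as `"-"`.
#' @param cds_by_taxon Named character vector (or `DNAStringSet`) of unaligned
#'   CDS, one per taxon in the alignment.
#' @return A [codon_alignment()].
#' @export
backtranslate <- function(protein_alignment, cds_by_taxon) {
  prot <- as.character(protein_alignment)
  if (is.null(names(prot))) names(prot) <- names(protein_alignment)
  cds <- as.character(cds_by_taxon)
  if (is.null(names(cds))) names(cds) <- names(cds_by_taxon)
  if (!all(names(prot) %in% names(cds))) stop("missing CDS for some taxa")
  w <- unique(nchar(prot))
  if (length(w) != 1L) stop("protein alignment rows differ in length")
  rows <- lapply(names(prot), function(tx) {
    aachars <- strsplit(prot[[tx]], "")[[1]]
    seq_nt <- cds[[tx]]
    n_res <- sum(aachars != "-")
    if (nchar(seq_nt) == 3L * (n_res + 1L)) {
      last <- substr(seq_nt, nchar(seq_nt) - 2L, nchar(seq_nt))
      if (Biostrings::GENETIC_CODE[[last]] == "*")
        seq_nt <- substr(seq_nt, 1L, nchar(seq_nt) - 3L)
    }
    if (nchar(seq_nt) != 3L * n_res)
      stop("CDS length does not match protein row for taxon ", tx)
    codons <- substring(seq_nt, seq(1, nchar(seq_nt), 3), seq(3, nchar(seq_nt), 3))
    trans <- translate_codon_vector(codons)
    mism <- which(trans != aachars[aachars != "-"])
    if (length(mism) > 0L)
      stop("translation mismatch for taxon ", tx, " at residue ", mism[1])
    out <- rep("---", w)
    out[aachars != "-"] <- codons
    out
  })
  codons <- do.call(rbind, rows)
  rownames(codons) <- names(prot)
  codon_alignment(codons)
}

#' Attach column confidence scores to an alignment
#'
#' @param aln A [codon_alignment()].
#' @param score_table Data frame with columns `column_index` (1-based
#'   amino-acid column) and `score` in `[0, 1]`, covering every column exactly
#'   once.
#' @return The alignment with scores attached.
#' @export
attach_column_scores <- function(aln, score_table) {
  stopifnot(all(c("column_index", "score") %in% names(score_table)))
  nc <- n_codons(aln)
  idx <- score_table$column_index
  if (anyDuplicated(idx) || !setequal(idx, seq_len(nc)))
    stop("score table must index every alignment column exactly once")
  if (any(score_table$score < 0 | score_table$score > 1))
    stop("column scores must lie in [0, 1]")
  aln$scores <- score_table$score[order(idx)]
  aln
}

#' Map an alignment column to per-taxon and genomic coordinates
#'
#' Returns, for one amino-acid column and taxon, the taxon's own ungapped
#' residue position (1-based) and, when a GFF3 gene model is supplied, the
#' three genomic positions of the codon. Reverse-strand codons are reported
#' in ascending genomic order with the strand flag. A taxon gapped at the
#' column yields `NA` coordinates rather than an error.
#'
#' @param aln A [codon_alignment()].
#' @param aa_column 1-based alignment column.
#' @param taxon Taxon name.
#' @param gff Optional GFF3 path or `GRanges` with CDS features.
#' @param gene_id Gene identifier used to select CDS features from `gff`.
#' @return List with `aa_column`, `taxon`, `ungapped_pos`, and (with `gff`)
#'   `chrom`, `strand`, `genomic_pos` (ascending, length 3).
#' @export
map_site <- function(aln, aa_column, taxon, gff = NULL, gene_id = NULL) {
  nc <- n_codons(aln)
  if (aa_column < 1L || aa_column > nc) stop("alignment column out of range")
  if (!taxon %in% alignment_taxa(aln)) stop("unknown taxon: ", taxon)
  gaps <- gap_mask(aln)[taxon, ]
  res <- list(aa_column = aa_column, taxon = taxon)
  if (gaps[aa_column]) {
    res$ungapped_pos <- NA_integer_
    if (!is.null(gff)) {
      res$chrom <- NA_character_; res$strand <- NA_character_
      res$genomic_pos <- rep(NA_integer_, 3)
    }
    return(res)
  }
  pos <- sum(!gaps[seq_len(aa_column)])
  res$ungapped_pos <- pos
  if (!is.null(gff)) {
    cmap <- cds_coordinate_map(gff, gene_id)
    idx <- (3L * pos - 2L):(3L * pos)
    if (max(idx) > length(cmap$positions))
      stop("codon extends beyond annotated CDS for gene ", gene_id)
    gpos <- cmap$positions[idx]
    res$chrom <- cmap$chrom
    res$strand <- cmap$strand
    res$genomic_pos <- sort(gpos)
  }
  res
}

# Ordered genomic positions of a gene's CDS (5'->3' in transcript order).
# gff may be a path or a GRanges; CDS features are matched to gene_id via
# their ID / Parent / gene_id attributes.
cds_coordinate_map <- function(gff, gene_id) {
  gr <- if (inherits(gff, "GRanges")) gff else rtracklayer::import(gff)
  cds <- gr[!is.na(gr$type) & gr$type == "CDS"]
  meta <- S4Vectors::mcols(cds)
  hit <- rep(FALSE, length(cds))
  for (col in intersect(c("ID", "Parent", "gene_id", "Name"), names(meta))) {
    v <- meta[[col]]
    if (methods::is(v, "CharacterList")) v <- vapply(v, function(x)
      if (length(x)) x[[1]] else NA_character_, character(1))
    hit <- hit | (!is.na(v) & grepl(gene_id, v, fixed = TRUE))
  }
  cds <- cds[hit]
  if (length(cds) == 0L) stop("no CDS features found for gene ", gene_id)
  strand <- as.character(BiocGenerics::strand(cds)[1])
  ord <- order(BiocGenerics::start(cds), decreasing = (strand == "-"))
  cds <- cds[ord]
  positions <- unlist(lapply(seq_along(cds), function(i) {
    s <- BiocGenerics::start(cds)[i]; e <- BiocGenerics::end(cds)[i]
    if (strand == "-") seq(e, s) else seq(s, e)
  }))
  list(chrom = as.character(GenomicRanges::seqnames(cds))[1],
       strand = strand, positions = positions)
}
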