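#' @useDynLib psgscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Internal cache for codon bookkeeping shared by the rate matrix, the
# likelihood core and the simulator.
.psg_env <- new.env(parent = emptyenv())

#' Sense codons of the standard genetic code
#'
#' Returns the 61 sense codons (standard code; stops TAA, TAG, TGA excluded)
#' in the fixed order used throughout the package: T, C, A, G at each codon
#' position, fastest at the third position.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  codon_tables()$codons
}

# Amino acid for each sense codon, standard code.
codon_amino_acids <- function() {
  codon_tables()$aa
}

# Build (once) the codon index tables:
#   codons : 61 sense codons
#   aa     : translation of each
#   pairs  : integer matrix, one row per unordered single-nucleotide-difference
#            codon pair: columns i, j (1-based codon index), is_ts (transition),
#            is_syn (synonymous)
codon_tables <- function() {
  if (!is.null(.psg_env$tables)) return(.psg_env$tables)
  nt <- c("T", "C", "A", "G")
  grid <- expand.grid(p3 = nt, p2 = nt, p1 = nt, stringsAsFactors = FALSE)
  all64 <- paste0(grid$p1, grid$p2, grid$p3)
  gc <- Biostrings::GENETIC_CODE
  aa64 <- unname(gc[all64])
  keep <- aa64 != "*"
  codons <- all64[keep]
  aa <- aa64[keep]
  n <- length(codons)
  stopifnot(n == 61L)
  cmat <- do.call(rbind, strsplit(codons, ""))
  purines <- c("A", "G")
  rows <- vector("list", 600L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diffs <- which(cmat[i, ] != cmat[j, ])
      if (length(diffs) != 1L) next
      a <- cmat[i, diffs]; b <- cmat[j, diffs]
      is_ts <- (a %in% purines) == (b %in% purines)
      k <- k + 1L
      rows[[k]] <- c(i, j, as.integer(is_ts), as.integer(aa[i] == aa[j]))
    }
  }
  pairs <- do.call(rbind, rows[seq_len(k)])
  colnames(pairs) <- c("i", "j", "is_ts", "is_syn")
  pairs0 <- pairs
  pairs0[, 1:2] <- pairs0[, 1:2] - 1L  # 0-based copy for the compiled core
  .psg_env$tables <- list(codons = codons, aa = aa, pairs = pairs,
                          pairs0 = pairs0)
  .psg_env$tables
}

codon_index <- function(codon) {
  match(codon, codon_tables()$codons)
}

#' Codon equilibrium frequencies from an alignment
#'
#' Estimates the 61 sense-codon equilibrium frequencies from observed
#' sequences. `"F3x4"` (the default) uses position-specific nucleotide
#' frequencies, `"F1x4"` a single nucleotide frequency vector, and `"F61"`
#' the observed codon frequencies (with a pseudo-count so no sense codon has
#' zero mass).
#'
#' @param codon_mat Character matrix of codons (rows = sequences, columns =
#'   codon sites); gaps `"---"` and codons containing `N` are ignored.
#' @param method One of `"F3x4"`, `"F1x4"`, `"F61"`.
#' @return Numeric vector of length 61 summing to 1.
#' @export
codon_frequencies <- function(codon_mat, method = c("F3x4", "F1x4", "F61")) {
  method <- match.arg(method)
  tab <- codon_tables()
  obs <- as.vector(codon_mat)
  obs <- obs[!is.na(obs) & obs != "---" & !grepl("N", obs, fixed = TRUE)]
  if (length(obs) == 0L) stop("no ungapped codons to estimate frequencies from")
  nt <- c("T", "C", "A", "G")
  if (method == "F61") {
    counts <- table(factor(obs, levels = tab$codons))
    freqs <- (as.numeric(counts) + 0.5) / sum(as.numeric(counts) + 0.5)
    return(freqs / sum(freqs))
  }
  chars <- do.call(rbind, strsplit(obs, ""))
  cmat <- do.call(rbind, strsplit(tab$codons, ""))
  if (method == "F1x4") {
    f <- table(factor(as.vector(chars), levels = nt)) + 0.5
    f <- as.numeric(f) / sum(as.numeric(f))
    pos_f <- list(f, f, f)
  } else {
    pos_f <- lapply(1:3, function(p) {
      f <- table(factor(chars[, p], levels = nt)) + 0.5
      as.numeric(f) / sum(as.numeric(f))
    })
  }
  freqs <- vapply(seq_len(61L), function(i) {
    pos_f[[1]][match(cmat[i, 1], nt)] *
      pos_f[[2]][match(cmat[i, 2], nt)] *
      pos_f[[3]][match(cmat[i, 3], nt)]
  }, numeric(1))
  freqs / sum(freqs)
}

#' Uniform codon frequencies
#'
#' @return Numeric vector: 1/61 for each sense codon.
#' @export
uniform_codon_frequencies <- function() {
  rep(1 / 61, 61L)
}
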