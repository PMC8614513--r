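# Codon substitution model, R side. The compiled core has its own copy of
# the matrix construction; this R version backs the simulator and the
# exported single-matrix interface.

#' Codon instantaneous rate matrix
#'
#' Standard codon-model construction: for codons differing at exactly one
#' nucleotide, `q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]`;
#' codons differing at more than one position have rate zero; diagonals make
#' rows sum to zero. With `scale = TRUE` the matrix is normalised so the
#' expected number of substitutions per unit time is 1 at stationarity.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Equilibrium frequencies over the 61 sense codons.
#' @param scale Normalise to one expected substitution per unit time.
#' @return 61 x 61 rate matrix (dimnames = sense codons).
#' @export
codon_rate_matrix <- function(kappa, omega, pi = uniform_codon_frequencies(),
                              scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61L, all(pi >= 0),
            abs(sum(pi) - 1) < 1e-8)
  tab <- codon_tables()
  Q <- matrix(0, 61L, 61L, dimnames = list(tab$codons, tab$codons))
  p <- tab$pairs
  rate <- ifelse(p[, "is_ts"] == 1L, kappa, 1) *
    ifelse(p[, "is_syn"] == 1L, 1, omega)
  Q[cbind(p[, "i"], p[, "j"])] <- rate * pi[p[, "j"]]
  Q[cbind(p[, "j"], p[, "i"])] <- rate * pi[p[, "i"]]
  diag(Q) <- -rowSums(Q)
  if (scale) {
    r <- -sum(pi * diag(Q))
    if (r > 0) Q <- Q / r
  }
  Q
}

# Expected substitution rate of the unscaled matrix at stationarity.
codon_rate <- function(kappa, omega, pi) {
  Q <- codon_rate_matrix(kappa, omega, pi, scale = FALSE)
  -sum(pi * diag(Q))
}

#' Codon transition probability matrix
#'
#' `P(t) = exp(Qt)`, computed through the symmetric eigendecomposition of the
#' reversible rate matrix.
#'
#' @inheritParams codon_rate_matrix
#' @param t Branch length (>= 0), in expected substitutions per codon when
#'   `scale = TRUE`.
#' @return 61 x 61 stochastic matrix.
#' @export
codon_pmatrix <- function(kappa, omega, t, pi = uniform_codon_frequencies(),
                          scale = TRUE) {
  if (t < 0) stop("branch length must be >= 0")
  tab <- codon_tables()
  P <- cpp_codon_pmatrix(kappa, omega, pi, tab$pairs0, t, scale)
  dimnames(P) <- list(tab$codons, tab$codons)
  P
}
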