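# Site-class mixture likelihood over a labeled tree, computed by Felsenstein
# pruning in the compiled core. A "class spec" lists, per site class, the
# background omega, the foreground omega, and the mixture proportion; the
# branch-site, M0 and RELAX-style models are all instances.

#' Site-class specifications
#'
#' Constructors for the mixture models used by the scan:
#' * `m0_classes(omega)` — one class, same omega everywhere.
#' * `branch_site_classes(p0, p1, omega0, omega2)` — the branch-site model:
#'   class 0 (conserved, omega0 on all branches), class 1 (neutral, omega 1),
#'   class 2a (omega0 background, omega2 foreground), class 2b (1 background,
#'   omega2 foreground); `p2a = (1-p0-p1) p0/(p0+p1)`,
#'   `p2b = (1-p0-p1) p1/(p0+p1)`.
#' * `relax_classes(p0, p1, omega0, omega2, K)` — three shared classes
#'   (omega0, 1, omega2) on reference branches; test branches use each
#'   class omega raised to the power `K` (K < 1 relaxes selection).
#'
#' @param omega,omega0,omega2 Rate ratios; `omega0` in (0,1), `omega2 >= 1`.
#' @param p0,p1 Class proportions with `p0 + p1 <= 1`, `p0 + p1 > 0`.
#' @param K Selection intensity exponent (> 0).
#' @return List with `omega_bg`, `omega_fg`, `props`, `label`.
#' @export
m0_classes <- function(omega) {
  list(omega_bg = omega, omega_fg = omega, props = 1, label = "M0")
}

#' @rdname m0_classes
#' @export
branch_site_classes <- function(p0, p1, omega0, omega2) {
  check_branch_site_params(p0, p1, omega0, omega2)
  p2 <- max(0, 1 - p0 - p1)   # guard the p0 + p1 = 1 boundary roundoff
  p2a <- p2 * p0 / (p0 + p1)
  p2b <- p2 * p1 / (p0 + p1)
  list(
    omega_bg = c(omega0, 1, omega0, 1),
    omega_fg = c(omega0, 1, omega2, omega2),
    props = c(p0, p1, p2a, p2b),
    label = "branch_site"
  )
}

#' @rdname m0_classes
#' @export
relax_classes <- function(p0, p1, omega0, omega2, K) {
  stopifnot(K > 0)
  check_branch_site_params(p0, p1, omega0, omega2)
  list(
    omega_bg = c(omega0, 1, omega2),
    omega_fg = c(omega0^K, 1, omega2^K),
    props = c(p0, p1, max(0, 1 - p0 - p1)),
    label = "relax_style"
  )
}

check_branch_site_params <- function(p0, p1, omega0, omega2) {
  if (p0 < 0 || p1 < 0 || p0 + p1 > 1 + 1e-12)
    stop("invalid proportions: need p0, p1 >= 0 and p0 + p1 <= 1")
  if (p0 + p1 <= 0) stop("p0 + p1 must be positive")
  if (omega0 <= 0 || omega0 >= 1) stop("omega0 must lie in (0, 1)")
  if (omega2 < 1) stop("omega2 must be >= 1")
  invisible(TRUE)
}

# Collapse alignment columns to unique site patterns.
# Returns states (ntaxa x npat, NA = missing), weights, and the pattern index
# of each original column.
site_patterns <- function(states) {
  keys <- apply(states, 2, paste, collapse = ",")
  uk <- unique(keys)
  idx <- match(keys, uk)
  first <- match(uk, keys)
  list(states = states[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = length(uk))),
       index = idx)
}

#' Mixture log-likelihood of a codon alignment
#'
#' Per-site likelihood is the proportion-weighted sum over site classes of
#' the pruning likelihood with that class's branch-dependent omega. Gap and
#' N-masked cells are missing data (summed over states); an all-gap column
#' contributes log(1) = 0 and is flagged.
#'
#' @param aln A [codon_alignment()].
#' @param ltree A [labeled_tree()]; tip labels must match alignment taxa.
#' @param kappa Transition/transversion ratio.
#' @param classes A class spec from [m0_classes()] and friends.
#' @param pi Codon equilibrium frequencies (default estimated F3x4).
#' @return List: `total` log-likelihood, `per_site` vector, `class_lik`
#'   (classes x sites likelihood matrix), `rho` (scaling factor),
#'   `all_gap_columns` (indices).
#' @export
site_log_likelihood <- function(aln, ltree, kappa, classes,
                                pi = codon_frequencies(aln$codons)) {
  ed <- tree_edge_data(ltree)
  states <- alignment_states(aln)
  if (!setequal(rownames(states), ed$tip_labels))
    stop("alignment taxa do not match tree tips")
  states <- states[ed$tip_labels, , drop = FALSE]
  pat <- site_patterns(states)
  sm <- pat$states
  sm[is.na(sm)] <- -1L
  res <- cpp_class_site_liks(
    sm, ed$parent, ed$child, ed$blen, ed$fg, ed$nnode,
    kappa, pi, codon_tables()$pairs0,
    cbind(classes$omega_bg, classes$omega_fg), classes$props)
  f <- res$class_lik
  mix <- as.vector(classes$props %*% f)
  per_pat <- log(mix)
  per_site <- per_pat[pat$index]
  all_gap <- which(colSums(!is.na(states)) == 0L)
  list(total = sum(pat$weights * per_pat),
       per_site = per_site,
       class_lik = f[, pat$index, drop = FALSE],
       rho = res$rho,
       all_gap_columns = all_gap)
}

# Fast path used by the optimisers: patterns precomputed once per fit.
pattern_log_likelihood <- function(pat_states, weights, ed, kappa, classes, pi,
                                   want_class_lik = FALSE) {
  res <- cpp_class_site_liks(
    pat_states, ed$parent, ed$child, ed$blen, ed$fg, ed$nnode,
    kappa, pi, codon_tables()$pairs0,
    cbind(classes$omega_bg, classes$omega_fg), classes$props)
  mix <- as.vector(classes$props %*% res$class_lik)
  out <- list(total = sum(weights * log(mix)))
  if (want_class_lik) {
    out$class_lik <- res$class_lik
    out$rho <- res$rho
  }
  out
}
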