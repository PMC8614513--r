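# Bayes empirical Bayes identification of positively selected sites.
#
# The posterior probability that a site belongs to a foreground-selected
# class (2a or 2b) is computed by integrating the branch-site parameters
# (p0, p1, omega0, omega2) over a discrete grid: a triangular grid on the
# (p0, p1) simplex and uniform grids on omega0 in (0,1) and omega2 in
# (1, 11), each with `ngrid` points and a uniform prior. Grid points are
# weighted by the full-data likelihood at that point (empirical Bayes);
# kappa, branch lengths and the substitution-rate scale are held at their
# MLEs from the alternative fit.

#' Bayes empirical Bayes site posteriors
#'
#' @param aln A [codon_alignment()].
#' @param ltree A [labeled_tree()] (same foreground as the fit).
#' @param m0 The [fit_m0()] result providing fixed branch lengths.
#' @param alt A converged alternative [fit_branch_site()] result.
#' @param ngrid Grid points per parameter dimension (default 10).
#' @param threshold Posterior cutoff for calling a site selected
#'   (default 0.95, strict inequality).
#' @return List: `posterior` (per amino-acid column), `selected_sites`
#'   (columns with posterior > threshold), `threshold`.
#' @export
beb_site_posteriors <- function(aln, ltree, m0, alt, ngrid = 10,
                                threshold = 0.95) {
  if (!isTRUE(alt$converged)) stop("alternative fit did not converge")
  lt <- with_fitted_lengths(ltree, m0)
  fd <- fit_data(aln, lt, alt$pi)
  states_full <- alignment_states(aln)
  pat <- site_patterns(states_full[fd$ed$tip_labels, , drop = FALSE])

  # hold the substitution-rate scale at the M0 value, as in the fits
  rho_mle <- m0_scale(m0)

  w0_grid <- (seq_len(ngrid) - 0.5) / ngrid
  w2_grid <- 1 + 10 * (seq_len(ngrid) - 0.5) / ngrid
  # triangular grid on the proportion simplex
  simplex <- list()
  for (i in seq_len(ngrid)) {
    for (j in seq_len(ngrid)) {
      p0 <- (i - 0.5) / ngrid; p1 <- (j - 0.5) / ngrid
      if (p0 + p1 <= 1) simplex[[length(simplex) + 1L]] <- c(p0, p1)
    }
  }
  prop_mat <- do.call(rbind, lapply(simplex, function(p) {
    p2 <- 1 - p[1] - p[2]
    c(p[1], p[2], p2 * p[1] / (p[1] + p[2]), p2 * p[2] / (p[1] + p[2]))
  }))

  npat <- length(pat$weights)
  nsimplex <- nrow(prop_mat)
  npoints <- ngrid * ngrid * nsimplex
  log_w <- numeric(npoints)
  post_acc <- matrix(0, nrow = npoints, ncol = npat)
  row0 <- 0L
  for (i2 in seq_len(ngrid)) {
    for (i0 in seq_len(ngrid)) {
      cls <- list(omega_bg = c(w0_grid[i0], 1, w0_grid[i0], 1),
                  omega_fg = c(w0_grid[i0], 1, w2_grid[i2], w2_grid[i2]),
                  props = rep(0.25, 4))
      f <- cpp_class_site_liks(
        fd$states, fd$ed$parent, fd$ed$child, fd$ed$blen, fd$ed$fg,
        fd$ed$nnode, alt$kappa, fd$pi, codon_tables()$pairs0,
        cbind(cls$omega_bg, cls$omega_fg), cls$props,
        fixed_rho = rho_mle)$class_lik
      mix <- prop_mat %*% f                     # nsimplex x npat
      sel <- prop_mat[, 3:4] %*% f[3:4, , drop = FALSE]
      rows <- row0 + seq_len(nsimplex)
      log_w[rows] <- as.vector(log(mix) %*% pat$weights)
      post_acc[rows, ] <- sel / mix
      row0 <- row0 + nsimplex
    }
  }
  log_w <- log_w - max(log_w)
  w <- exp(log_w); w <- w / sum(w)
  post_pat <- as.vector(w %*% post_acc)
  posterior <- post_pat[pat$index]
  list(posterior = posterior,
       selected_sites = which(posterior > threshold),
       threshold = threshold)
}
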