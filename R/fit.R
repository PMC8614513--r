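# Maximum-likelihood fits: M0 (one ratio; estimates branch lengths),
# branch-site alternative/null, and the RELAX-style selection-intensity
# model. All optimisation runs in transformed space (log for kappa and
# branch lengths, multinomial logit for proportions, logit for omega0,
# offset log for omega2, log for K) from small sets of deterministic
# starting points; convergence is declared at a relative log-likelihood
# change below 1e-8 (L-BFGS-B).

OMEGA2_MAX <- 999

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# shared L-BFGS-B driver. With several deterministic starts, each is first
# explored with a short iteration budget; the best explored point is then
# polished to convergence (relative log-likelihood tolerance ~1e-8).
run_starts <- function(obj, starts, lower, upper, maxit = 200,
                       explore_maxit = 8) {
  one <- function(s, mi) {
    tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = mi, factr = 4.5e7)),
      error = function(e) NULL)
  }
  used <- length(starts)
  if (length(starts) > 1L) {
    explored <- lapply(starts, one, mi = explore_maxit)
    vals <- vapply(explored, function(f) if (is.null(f)) Inf else f$value,
                   numeric(1))
    if (all(!is.finite(vals))) return(NULL)
    best_start <- explored[[which.min(vals)]]$par
  } else {
    best_start <- starts[[1]]
  }
  fit <- one(best_start, maxit)
  if (is.null(fit)) return(NULL)
  list(par = fit$par, loglik = -fit$value, converged = fit$convergence == 0,
       restarts = used)
}

fit_data <- function(aln, ltree, pi) {
  ed <- tree_edge_data(ltree)
  states <- alignment_states(aln)
  if (!setequal(rownames(states), ed$tip_labels))
    stop("alignment taxa do not match tree tips")
  states <- states[ed$tip_labels, , drop = FALSE]
  pat <- site_patterns(states)
  sm <- pat$states
  sm[is.na(sm)] <- -1L
  list(ed = ed, states = sm, weights = pat$weights, pi = pi)
}

#' Fit the one-ratio (M0) codon model with free branch lengths
#'
#' Maximises the likelihood over kappa, a single omega shared by all sites
#' and branches, and all branch lengths. The fitted tree is the branch-length
#' stage for the branch-site and relaxation fits, which hold lengths fixed.
#'
#' @param aln A [codon_alignment()].
#' @param tree An `ape::phylo` topology (branch lengths used as one start).
#' @param pi Codon frequencies; default F3x4 from the alignment.
#' @param freq_method Used when `pi` is missing: `"F3x4"`, `"F1x4"`, `"F61"`.
#' @return List (`model = "M0"`): `loglik`, `kappa`, `omega`, `tree` (fitted
#'   branch lengths), `pi`, `converged`, `restarts`.
#' @export
fit_m0 <- function(aln, tree, pi = NULL,
                   freq_method = c("F3x4", "F1x4", "F61")) {
  freq_method <- match.arg(freq_method)
  if (is.null(pi)) pi <- codon_frequencies(aln$codons, freq_method)
  ltree <- labeled_tree(tree, tree$tip.label[1])
  fd <- fit_data(aln, ltree, pi)
  ne <- length(fd$ed$blen)
  obj <- function(x) {
    kappa <- exp(x[1]); omega <- exp(x[2])
    ed <- fd$ed
    ed$blen <- exp(x[3:(2 + ne)])
    ll <- tryCatch(
      pattern_log_likelihood(fd$states, fd$weights, ed, kappa,
                             m0_classes(omega), fd$pi)$total,
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  t0 <- pmax(fd$ed$blen, 1e-4)
  starts <- list(c(log(2), log(0.3), log(t0)))
  lower <- c(log(0.05), log(1e-4), rep(log(1e-7), ne))
  upper <- c(log(50), log(20), rep(log(8), ne))
  res <- run_starts(obj, starts, lower, upper)
  if (is.null(res)) return(list(model = "M0", converged = FALSE))
  fitted <- ltree
  fitted$tree <- ape::reorder.phylo(ltree$tree, "postorder")
  fitted$tree$edge.length <- exp(res$par[3:(2 + ne)])
  list(model = "M0", loglik = res$loglik,
       kappa = exp(res$par[1]), omega = exp(res$par[2]),
       tree = fitted$tree, pi = pi,
       converged = res$converged, restarts = res$restarts)
}

# labeled tree carrying the M0-fitted branch lengths
with_fitted_lengths <- function(ltree, m0) {
  lt <- labeled_tree(m0$tree, ltree$foreground)
  lt
}

# The M0-scale convention: branch lengths come from the M0 fit and the
# substitution-rate normalisation of every subsequent mixture fit is held
# at the M0 value rho0 = rate(Q(kappa_M0, omega_M0)). With the scale fixed,
# the per-class site likelihoods depend only on (kappa, class omegas), so
# the class proportions can be profiled out by a cheap inner optimisation
# that reuses the cached likelihoods (profile likelihood).
m0_scale <- function(m0) codon_rate(m0$kappa, m0$omega, m0$pi)

# per-class pattern likelihoods at fixed scale
class_lik_fixed_scale <- function(fd, kappa, omega_bg, omega_fg, rho0) {
  cpp_class_site_liks(
    fd$states, fd$ed$parent, fd$ed$child, fd$ed$blen, fd$ed$fg, fd$ed$nnode,
    kappa, fd$pi, codon_tables()$pairs0,
    cbind(omega_bg, omega_fg), rep(1 / length(omega_bg), length(omega_bg)),
    fixed_rho = rho0)$class_lik
}

# inner profile over proportions: props = map(z) for a 2-parameter
# multinomial-logit z; map encodes the model's proportion constraint
profile_props <- function(f, weights, prop_map, z_start) {
  inner <- function(z) {
    pr <- prop_map(z)
    mix <- as.vector(pr %*% f)
    if (any(mix <= 0)) return(1e10)
    -sum(weights * log(mix))
  }
  # Nelder-Mead: reentrant (this runs inside the outer L-BFGS-B objective)
  fit <- stats::optim(pmin(pmax(z_start, -12), 12), inner,
                      method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  list(z = fit$par, loglik = -fit$value)
}

simplex2 <- function(z) {
  e1 <- exp(z[1]); e2 <- exp(z[2])
  c(e1, e2) / (1 + e1 + e2)
}

#' Fit the branch-site model (alternative or null)
#'
#' The alternative maximises over kappa, p0, p1, omega0 in (0,1) and omega2
#' in `[1, 999]`; the null fixes omega2 = 1. Branch lengths (and the
#' substitution-rate scale) are taken from the M0 fit and held fixed; the
#' class proportions are profiled out at every outer parameter point.
#' Deterministic multi-start.
#'
#' @param aln A [codon_alignment()].
#' @param ltree A [labeled_tree()] naming the foreground branch.
#' @param m0 Result of [fit_m0()] on the same alignment.
#' @param null Fit the null model (omega2 fixed at 1)?
#' @param null_fit Optional converged null fit; its solution seeds an extra
#'   alternative start so the nesting inequality cannot be lost to a local
#'   optimum.
#' @return List (`model = "branch_site_alt"` or `"..._null"`): `loglik`,
#'   `kappa`, `p0`, `p1`, `p2a`, `p2b`, `omega0`, `omega2`, `pi`,
#'   `converged`, `restarts`.
#' @export
fit_branch_site <- function(aln, ltree, m0, null = FALSE, null_fit = NULL) {
  if (!isTRUE(m0$converged)) stop("M0 branch-length fit did not converge")
  lt <- with_fitted_lengths(ltree, m0)
  fd <- fit_data(aln, lt, m0$pi)
  rho0 <- m0_scale(m0)
  z_env <- new.env()
  z_env$z <- c(log(0.75 / 0.1), log(0.15 / 0.1))
  prop_map <- function(z) {
    p01 <- simplex2(z)
    p0 <- p01[1]; p1 <- p01[2]; p2 <- 1 - p0 - p1
    c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
  }
  obj <- function(x) {
    kappa <- exp(x[1])
    omega0 <- inv_logit(x[2])
    omega2 <- if (null) 1 else 1 + exp(x[3])
    f <- tryCatch(
      class_lik_fixed_scale(fd, kappa,
                            c(omega0, 1, omega0, 1),
                            c(omega0, 1, omega2, omega2), rho0),
      error = function(e) NULL)
    if (is.null(f)) return(1e10)
    pro <- profile_props(f, fd$weights, prop_map, z_env$z)
    z_env$z <- pro$z
    if (!is.finite(pro$loglik)) 1e10 else -pro$loglik
  }
  w0_start <- logit(min(0.8, max(0.05, m0$omega)))
  k_start <- log(max(m0$kappa, 0.1))
  if (null) {
    starts <- list(c(k_start, w0_start), c(k_start, logit(0.2)))
    lower <- c(log(0.05), logit(1e-4))
    upper <- c(log(50), logit(1 - 1e-4))
  } else {
    starts <- list(c(k_start, w0_start, log(0.5)),
                   c(k_start, w0_start, log(3.5)),
                   c(k_start, logit(0.2), log(9)))
    if (!is.null(null_fit) && isTRUE(null_fit$converged))
      starts <- c(starts, list(c(log(null_fit$kappa),
                                 logit(null_fit$omega0), log(1e-5))))
    lower <- c(log(0.05), logit(1e-4), log(1e-6))
    upper <- c(log(50), logit(1 - 1e-4), log(OMEGA2_MAX - 1))
  }
  res <- run_starts(obj, starts, lower, upper)
  if (is.null(res))
    return(list(model = if (null) "branch_site_null" else "branch_site_alt",
                converged = FALSE))
  x <- res$par
  # final inner polish at the outer optimum
  kappa <- exp(x[1]); omega0 <- inv_logit(x[2])
  omega2 <- if (null) 1 else 1 + exp(x[3])
  f <- class_lik_fixed_scale(fd, kappa, c(omega0, 1, omega0, 1),
                             c(omega0, 1, omega2, omega2), rho0)
  pro <- profile_props(f, fd$weights, prop_map, z_env$z)
  pr <- prop_map(pro$z)
  list(model = if (null) "branch_site_null" else "branch_site_alt",
       loglik = pro$loglik, kappa = kappa,
       p0 = pr[1], p1 = pr[2], p2a = pr[3], p2b = pr[4],
       omega0 = omega0, omega2 = omega2,
       pi = m0$pi, foreground = ltree$foreground, rho0 = rho0,
       converged = res$converged, restarts = res$restarts)
}

#' Likelihood-ratio test
#'
#' Statistic `2 * (l_alt - l_null)`, clamped at zero against numerical
#' jitter, referred to the upper tail of chi-squared. The default df = 1 and
#' the plain chi-squared reference match common branch-site practice (the
#' 50:50 point-mass mixture would halve the p-value; the plain reference is
#' conservative).
#'
#' @param l_alt,l_null Log-likelihoods of nested fits.
#' @param df Degrees of freedom.
#' @return List: `statistic`, `df`, `p`.
#' @export
lrt <- function(l_alt, l_null, df = 1) {
  stopifnot(is.finite(l_alt), is.finite(l_null))
  stat <- max(0, 2 * (l_alt - l_null))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Branch-site likelihood-ratio test for one gene and branch
#'
#' Convenience wrapper: alternative and null branch-site fits plus the LRT.
#'
#' @inheritParams fit_branch_site
#' @return List: `alt`, `null`, `lrt`.
#' @export
branch_site_test <- function(aln, ltree, m0) {
  nul <- fit_branch_site(aln, ltree, m0, null = TRUE)
  alt <- fit_branch_site(aln, ltree, m0, null = FALSE, null_fit = nul)
  if (!isTRUE(alt$converged) || !isTRUE(nul$converged))
    return(list(alt = alt, null = nul, lrt = NULL))
  list(alt = alt, null = nul, lrt = lrt(alt$loglik, nul$loglik))
}

#' Fit the RELAX-style selection-intensity model
#'
#' Three site classes (omega0 < 1, 1, omega2 >= 1) shared by all branches;
#' on the test (foreground) branches every class omega is raised to the power
#' K. The alternative leaves K free; the null fixes K = 1; the LRT has one
#' degree of freedom. `K < 1` signals relaxed selection on the test branches.
#' This is a deliberate simplification of the published RELAX formulation
#' (three shared classes, one K) and is labelled `relax_style` everywhere;
#' no bit-compatibility with external tools is claimed.
#'
#' @inheritParams fit_branch_site
#' @return List: `K`, `loglik_alt`, `loglik_null`, `p`, parameter MLEs,
#'   `converged`.
#' @export
fit_relax_style <- function(aln, ltree, m0) {
  if (!isTRUE(m0$converged)) stop("M0 branch-length fit did not converge")
  lt <- with_fitted_lengths(ltree, m0)
  fd <- fit_data(aln, lt, m0$pi)
  rho0 <- m0_scale(m0)
  z_env <- new.env()
  z_env$z <- c(log(0.7 / 0.1), log(0.2 / 0.1))
  prop_map <- function(z) {
    p01 <- simplex2(z)
    c(p01[1], p01[2], 1 - p01[1] - p01[2])
  }
  obj_factory <- function(fix_K) {
    function(x) {
      kappa <- exp(x[1])
      omega0 <- inv_logit(x[2])
      omega2 <- 1 + exp(x[3])
      K <- if (is.null(fix_K)) exp(x[4]) else fix_K
      f <- tryCatch(
        class_lik_fixed_scale(fd, kappa,
                              c(omega0, 1, omega2),
                              c(omega0^K, 1, omega2^K), rho0),
        error = function(e) NULL)
      if (is.null(f)) return(1e10)
      pro <- profile_props(f, fd$weights, prop_map, z_env$z)
      z_env$z <- pro$z
      if (!is.finite(pro$loglik)) 1e10 else -pro$loglik
    }
  }
  base <- c(log(max(m0$kappa, 0.1)),
            logit(min(0.8, max(0.05, m0$omega))), log(1))
  lower3 <- c(log(0.05), logit(1e-4), log(1e-6))
  upper3 <- c(log(50), logit(1 - 1e-4), log(OMEGA2_MAX - 1))
  nul <- run_starts(obj_factory(1), list(base, c(base[1], logit(0.2), log(3))),
                    lower3, upper3)
  alt <- run_starts(obj_factory(NULL),
                    list(c(base, log(0.3)), c(base, log(1)), c(base, log(3))),
                    c(lower3, log(0.02)), c(upper3, log(50)))
  if (is.null(alt) || is.null(nul))
    return(list(model = "relax_style", converged = FALSE))
  # K = 1 is nested in K free: guard the alternative from local optima below
  # the null by polishing from the null solution as well
  if (alt$loglik < nul$loglik) {
    alt2 <- run_starts(obj_factory(NULL), list(c(nul$par, log(1))),
                       c(lower3, log(0.02)), c(upper3, log(50)))
    if (!is.null(alt2) && alt2$loglik > alt$loglik) alt <- alt2
  }
  x <- alt$par
  kappa <- exp(x[1]); omega0 <- inv_logit(x[2]); omega2 <- 1 + exp(x[3])
  K <- exp(x[4])
  f <- class_lik_fixed_scale(fd, kappa, c(omega0, 1, omega2),
                             c(omega0^K, 1, omega2^K), rho0)
  pro <- profile_props(f, fd$weights, prop_map, z_env$z)
  pr <- prop_map(pro$z)
  cmp <- lrt(max(alt$loglik, pro$loglik), nul$loglik)
  list(model = "relax_style",
       K = exp(x[4]),
       loglik_alt = alt$loglik, loglik_null = nul$loglik,
       statistic = cmp$statistic, p = cmp$p,
       kappa = exp(x[1]), p0 = pr[1], p1 = pr[2],
       omega0 = inv_logit(x[2]), omega2 = 1 + exp(x[3]),
       foreground = ltree$foreground, rho0 = rho0,
       converged = alt$converged && nul$converged,
       restarts = alt$restarts + nul$restarts)
}
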