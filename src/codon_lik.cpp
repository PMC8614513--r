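// Codon substitution likelihood core.
//
// Rate matrices follow the standard codon-model construction: instantaneous
// rate between codons differing at one nucleotide is pi_j * kappa^[transition]
// * omega^[nonsynonymous]; multi-step changes have rate zero. The model is
// time-reversible, so P(t) = exp(Qt) is computed through the symmetric
// eigendecomposition of D^{1/2} Q D^{-1/2} (D = diag(pi)).
//
// The mixture likelihood sums, per site, over site classes whose omega may
// differ between foreground and background branches (branch-site and
// RELAX-style models are both instances). Pruning runs over a postorder edge
// list; leaf states are column gathers, missing data (gaps, N codons) are
// all-ones partials.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Unscaled GY-style rate matrix. pairs: npair x 4 (i, j, is_ts, is_syn),
// 0-based codon indices.
static mat build_Q(double kappa, double omega, const vec& pi,
                   const imat& pairs) {
  const uword n = pi.n_elem;
  mat Q(n, n, fill::zeros);
  for (uword r = 0; r < pairs.n_rows; ++r) {
    const uword i = pairs(r, 0), j = pairs(r, 1);
    double rate = pairs(r, 2) ? kappa : 1.0;
    if (!pairs(r, 3)) rate *= omega;
    Q(i, j) = rate * pi(j);
    Q(j, i) = rate * pi(i);
  }
  Q.diag() = -sum(Q, 1);
  return Q;
}

struct EigQ {
  vec eval;
  mat U;     // D^{-1/2} V
  mat V;     // V^t D^{1/2}
  double rate;  // -sum_i pi_i q_ii of the unscaled matrix
};

static EigQ eig_of_Q(double kappa, double omega, const vec& pi,
                     const imat& pairs) {
  mat Q = build_Q(kappa, omega, pi, pairs);
  EigQ out;
  out.rate = -dot(pi, Q.diag());
  vec sq = sqrt(pi);
  mat B = (Q.each_col() % sq);        // diag(sq) * Q
  B.each_row() /= sq.t();             //          * diag(1/sq)
  B = 0.5 * (B + B.t());
  vec eval;
  mat evec;
  eig_sym(eval, evec, B);
  out.eval = eval;
  out.U = evec.each_col() / sq;
  out.V = (evec.each_col() % sq).t();
  return out;
}

static mat prob_matrix(const EigQ& e, double t) {
  mat P = e.U * diagmat(exp(e.eval * t)) * e.V;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// Per-class per-pattern site likelihoods for a mixture codon model.
//
// states:   ntip x npat integer matrix, 0-based codon states, -1 = missing
// parent/child: postorder edge list, 0-based node ids (tips are 0..ntip-1)
// blen:     branch lengths (expected substitutions per codon, background
//           mixture scale)
// fg:       1 if the edge is foreground, else 0
// omega_classes: nclass x 2 (background, foreground omega)
// props:    class proportions used for the scaling factor
//
// Branch lengths are interpreted on the background-mixture scale: every
// class rate matrix is divided by rho = sum_k props_k * rate(Q(omega_bg_k)),
// so t is the expected number of substitutions per codon for a site evolving
// under the background regime.
// [[Rcpp::export]]
Rcpp::List cpp_class_site_liks(const arma::imat& states,
                               const arma::ivec& parent,
                               const arma::ivec& child,
                               const arma::vec& blen,
                               const arma::ivec& fg,
                               int nnode,
                               double kappa,
                               const arma::vec& pi,
                               const arma::imat& pairs,
                               const arma::mat& omega_classes,
                               const arma::vec& props,
                               double fixed_rho = -1.0) {
  const uword ntip = states.n_rows;
  const uword npat = states.n_cols;
  const uword nedge = parent.n_elem;
  const uword nclass = omega_classes.n_rows;

  // unique omegas across (class, bg/fg)
  std::vector<double> uomega;
  umat oidx(nclass, 2);
  for (uword k = 0; k < nclass; ++k) {
    for (uword s = 0; s < 2; ++s) {
      double w = omega_classes(k, s);
      uword found = uomega.size();
      for (uword u = 0; u < uomega.size(); ++u)
        if (std::abs(uomega[u] - w) < 1e-14) { found = u; break; }
      if (found == uomega.size()) uomega.push_back(w);
      oidx(k, s) = found;
    }
  }
  std::vector<EigQ> eigs;
  eigs.reserve(uomega.size());
  for (double w : uomega) eigs.push_back(eig_of_Q(kappa, w, pi, pairs));

  double rho = fixed_rho;
  if (!(rho > 0.0)) {
    rho = 0.0;
    for (uword k = 0; k < nclass; ++k) rho += props(k) * eigs[oidx(k, 0)].rate;
  }
  if (!(rho > 0.0)) Rcpp::stop("degenerate substitution rate (rho <= 0)");

  // P matrices cached per (unique omega, edge)
  std::vector<std::vector<mat>> Pcache(uomega.size());
  std::vector<std::vector<bool>> Phave(uomega.size());
  for (uword u = 0; u < uomega.size(); ++u) {
    Pcache[u].resize(nedge);
    Phave[u].assign(nedge, false);
  }

  // classes with identical (background, foreground) omega pairs share the
  // same site likelihoods; compute each distinct pair once
  mat f(nclass, npat);
  std::vector<int> done(nclass, -1);
  for (uword k = 0; k < nclass; ++k) {
    for (uword k2 = 0; k2 < k; ++k2) {
      if (oidx(k, 0) == oidx(k2, 0) && oidx(k, 1) == oidx(k2, 1)) {
        done[k] = (int)k2;
        break;
      }
    }
  }
  for (uword k = 0; k < nclass; ++k) {
    if (done[k] >= 0) {
      f.row(k) = f.row(done[k]);
      continue;
    }
    std::vector<mat> partial(nnode);
    std::vector<bool> seen(nnode, false);
    for (uword e = 0; e < nedge; ++e) {
      const uword pa = parent(e), ch = child(e);
      const uword u = oidx(k, fg(e) ? 1 : 0);
      if (!Phave[u][e]) {
        Pcache[u][e] = prob_matrix(eigs[u], blen(e) / rho);
        Phave[u][e] = true;
      }
      const mat& P = Pcache[u][e];
      mat contrib;
      if (ch < ntip) {
        contrib.set_size(pi.n_elem, npat);
        for (uword s = 0; s < npat; ++s) {
          int st = states(ch, s);
          if (st < 0) contrib.col(s).ones();
          else contrib.col(s) = P.col(st);
        }
      } else {
        contrib = P * partial[ch];
        partial[ch].reset();
      }
      if (!seen[pa]) {
        partial[pa] = std::move(contrib);
        seen[pa] = true;
      } else {
        partial[pa] %= contrib;
      }
    }
    const uword root = parent(nedge - 1);
    f.row(k) = pi.t() * partial[root];
  }
  return Rcpp::List::create(Rcpp::Named("class_lik") = f,
                            Rcpp::Named("rho") = rho);
}

// Transition probability matrix for a single omega, exported for reuse by
// the simulator and for direct testing of the matrix exponential path.
// t is on the scale of the *unscaled* Q unless scale = true, in which case
// Q is normalised to one expected substitution per unit time.
// [[Rcpp::export]]
arma::mat cpp_codon_pmatrix(double kappa, double omega, const arma::vec& pi,
                            const arma::imat& pairs, double t, bool scale) {
  EigQ e = eig_of_Q(kappa, omega, pi, pairs);
  double tt = scale ? t / e.rate : t;
  return prob_matrix(e, tt);
}

// Unscaled rate matrix, exported for tests.
// [[Rcpp::export]]
arma::mat cpp_codon_qmatrix(double kappa, double omega, const arma::vec& pi,
                            const arma::imat& pairs) {
  return build_Q(kappa, omega, pi, pairs);
}
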