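// Felsenstein pruning log-likelihood for a k-state CTMC on a rooted
// tree. Edges must be supplied in postorder (children before parents).
// P(t) = exp(Qt) is computed from one eigendecomposition of Q shared
// across edges, with a per-edge Pade expmat fallback when Q is close
// to defective.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// robust matrix exponential: scaling-and-squaring with a Taylor core
// (never throws, unlike the Pade routine on ill-conditioned input)
static arma::mat expmSS(const arma::mat& A) {
  const double nrm = arma::norm(A, "inf");
  int s = 0;
  double scale = 1.0;
  while (nrm * scale > 0.5 && s < 60) { scale *= 0.5; ++s; }
  arma::mat B = A * scale;
  arma::mat P = arma::eye(A.n_rows, A.n_cols);
  arma::mat term = P;
  for (int i = 1; i <= 16; ++i) {
    term = term * B / static_cast<double>(i);
    P += term;
  }
  for (int i = 0; i < s; ++i) P = P * P;
  return P;
}

// [[Rcpp::export(name = ".pruningLogLikCpp")]]
double pruningLogLikCpp(const arma::imat& edge,
                        const arma::vec& edgeLength,
                        const int nTip,
                        const arma::mat& tipL,
                        const arma::mat& Q,
                        const arma::vec& prior) {
  const int k = Q.n_rows;
  const int nEdge = edge.n_rows;
  int nNode = nTip;
  for (int e = 0; e < nEdge; ++e) {
    if (edge(e, 0) > nNode) nNode = edge(e, 0);
    if (edge(e, 1) > nNode) nNode = edge(e, 1);
  }
  arma::mat L(nNode, k);
  L.rows(0, nTip - 1) = tipL;
  L.rows(nTip, nNode - 1).ones();

  // eigendecomposition of Q (shared across edges)
  bool useEig = false;
  arma::cx_vec eigval;
  arma::cx_mat U, Uinv;
  if (arma::eig_gen(eigval, U, Q)) {
    arma::cx_mat Ui;
    if (arma::inv(Ui, U)) {
      arma::mat recon = arma::real(U * arma::diagmat(eigval) * Ui);
      if (arma::norm(recon - Q, "inf") <
          1e-8 * std::max(1.0, arma::norm(Q, "inf"))) {
        useEig = true;
        Uinv = Ui;
      }
    }
  }

  double logScale = 0.0;
  arma::mat P(k, k);
  for (int e = 0; e < nEdge; ++e) {
    const int child = edge(e, 1) - 1;
    const int parent = edge(e, 0) - 1;
    const double t = edgeLength(e);
    if (useEig) {
      P = arma::real(U * arma::diagmat(arma::exp(eigval * t)) * Uinv);
      P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    } else {
      P = expmSS(Q * t);
    }
    arma::rowvec v = L.row(child) * P.t();
    L.row(parent) %= v;
    const double m = L.row(parent).max();
    if (m > 0.0 && m < 1e-100) {
      L.row(parent) /= m;
      logScale += std::log(m);
    }
  }
  const double lik = arma::dot(prior, L.row(nTip).t());
  if (lik <= 0.0 || !std::isfinite(lik)) return -arma::datum::inf;
  return std::log(lik) + logScale;
}
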