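#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// epsilon-insensitive support vector regression solved by SMO on the
// standard 2n-variable dual:
//
//   min over (alpha, alpha*) in [0,C]^2n, sum(alpha - alpha*) = 0 of
//   1/2 (a-a*)' K (a-a*) + eps * sum(a+a*) - y'(a-a*)
//
// kernel_type: 0 = linear, 1 = Gaussian RBF with parameter gamma.
// Working-set selection is second-order (maximal violating i, then the j
// minimizing the 2-variable objective decrease) when the kernel matrix is
// held in memory (n <= 8000); beyond that a first-order linear-kernel path
// maintains the primal weight vector instead of the kernel matrix.
// [[Rcpp::export]]
List svr_smo_cpp(const arma::mat& X, const arma::vec& y, double C, double eps,
                 int kernel_type, double gamma, double tol, double max_iter, bool verbose = false) {
  const arma::uword n = X.n_rows;
  const bool use_K = (kernel_type == 1) || (n <= 8000);
  arma::mat K;
  if (use_K) {
    if (kernel_type == 0) {
      K = X * X.t();
    } else {
      arma::vec sq = arma::sum(arma::square(X), 1);
      K = arma::repmat(sq, 1, n) + arma::repmat(sq.t(), n, 1) - 2.0 * (X * X.t());
      K = arma::exp(-gamma * arma::clamp(K, 0.0, arma::datum::inf));
    }
  }
  arma::vec diagK = use_K ? arma::vec(K.diag())
                          : arma::vec(arma::sum(arma::square(X), 1));

  arma::vec a_up(n, arma::fill::zeros), a_dn(n, arma::fill::zeros);
  arma::vec f(n, arma::fill::zeros);
  arma::vec w(X.n_cols, arma::fill::zeros);
  long long iter = 0;
  const long long iter_cap = (long long)max_iter;
  bool converged = false;
  const double tau = 1e-12;

  while (iter < iter_cap) {
    // i: maximal -s_t G_t over I_up; M: minimum over I_low (stopping)
    double m = -arma::datum::inf, M = arma::datum::inf;
    arma::sword ii = -1;
    for (arma::uword b = 0; b < n; ++b) {
      const double vup = y[b] - f[b] - eps;  // -sG for alpha_b
      const double vdn = y[b] - f[b] + eps;  // -sG for alpha*_b
      if (a_up[b] < C && vup > m) { m = vup; ii = (arma::sword)b; }
      if (a_dn[b] > 0 && vdn > m) { m = vdn; ii = (arma::sword)(b + n); }
      if (a_up[b] > 0 && vup < M) M = vup;
      if (a_dn[b] < C && vdn < M) M = vdn;
    }
    if (verbose && iter % 100000 == 0) {
      Rcout << "iter " << iter << " gap " << (m - M)
            << " nSV " << arma::accu((a_up - a_dn) != 0) << "\n";
    }
    if (ii < 0 || m - M < tol) { converged = true; break; }
    const arma::uword bi = (arma::uword)ii % n;

    // j over I_low: second-order when K is available, else first-order
    arma::sword jj = -1;
    if (use_K) {
      double best = arma::datum::inf;
      const double Kii = diagK[bi];
      const double* Kbi = K.colptr(bi);  // K symmetric: column = row
      for (arma::uword b = 0; b < n; ++b) {
        const double vup = y[b] - f[b] - eps;
        const double vdn = y[b] - f[b] + eps;
        double quad = Kii + diagK[b] - 2.0 * Kbi[b];
        if (quad < tau) quad = tau;
        if (a_up[b] > 0 && vup < m) {
          const double bd = m - vup, obj = -bd * bd / quad;
          if (obj < best) { best = obj; jj = (arma::sword)b; }
        }
        if (a_dn[b] < C && vdn < m) {
          const double bd = m - vdn, obj = -bd * bd / quad;
          if (obj < best) { best = obj; jj = (arma::sword)(b + n); }
        }
      }
    } else {
      double best = arma::datum::inf;
      for (arma::uword b = 0; b < n; ++b) {
        const double vup = y[b] - f[b] - eps;
        const double vdn = y[b] - f[b] + eps;
        if (a_up[b] > 0 && vup < best) { best = vup; jj = (arma::sword)b; }
        if (a_dn[b] < C && vdn < best) { best = vdn; jj = (arma::sword)(b + n); }
      }
    }
    if (jj < 0) { converged = true; break; }
    const arma::uword bj = (arma::uword)jj % n;
    const double vj = (jj < (arma::sword)n) ? (y[bj] - f[bj] - eps)
                                            : (y[bj] - f[bj] + eps);

    const double Kij = use_K ? K(bi, bj) : arma::dot(X.row(bi), X.row(bj));
    double quad = diagK[bi] + diagK[bj] - 2.0 * Kij;
    if (quad < tau) quad = tau;
    double t = (m - vj) / quad;
    const double cap_i = (ii < (arma::sword)n) ? (C - a_up[bi]) : a_dn[bi];
    const double cap_j = (jj < (arma::sword)n) ? a_up[bj] : (C - a_dn[bj]);
    if (t > cap_i) t = cap_i;
    if (t > cap_j) t = cap_j;
    if (!(t > 0)) { converged = true; break; }  // numerical stall

    if (ii < (arma::sword)n) a_up[bi] += t; else a_dn[bi] -= t;
    if (jj < (arma::sword)n) a_up[bj] -= t; else a_dn[bj] += t;
    // beta_bi += t, beta_bj -= t
    if (use_K) {
      f += t * (K.col(bi) - K.col(bj));
    } else {
      w += t * (X.row(bi).t() - X.row(bj).t());
      f = X * w;
    }
    ++iter;
  }

  arma::vec beta = a_up - a_dn;

  // intercept from KKT: average -s_t G_t over free variables, else midpoint
  double bsum = 0.0; arma::uword nfree = 0;
  double m = -arma::datum::inf, M = arma::datum::inf;
  for (arma::uword b = 0; b < n; ++b) {
    const double vup = y[b] - f[b] - eps;
    const double vdn = y[b] - f[b] + eps;
    if (a_up[b] > 0 && a_up[b] < C) { bsum += vup; ++nfree; }
    if (a_dn[b] > 0 && a_dn[b] < C) { bsum += vdn; ++nfree; }
    if (a_up[b] < C && vup > m) m = vup;
    if (a_dn[b] > 0 && vdn > m) m = vdn;
    if (a_up[b] > 0 && vup < M) M = vup;
    if (a_dn[b] < C && vdn < M) M = vdn;
  }
  double bias;
  if (nfree > 0) bias = bsum / (double)nfree;
  else if (std::isfinite(m) && std::isfinite(M)) bias = 0.5 * (m + M);
  else bias = arma::mean(y);

  if (kernel_type == 0) w = X.t() * beta;  // explicit weights, linear kernel

  return List::create(
    _["beta"] = beta, _["bias"] = bias, _["w"] = w,
    _["iterations"] = (double)iter, _["converged"] = converged
  );
}

// Gaussian RBF kernel block K(A, B), used at prediction time.
// [[Rcpp::export]]
arma::mat rbf_kernel_cpp(const arma::mat& A, const arma::mat& B, double gamma) {
  arma::vec sa = arma::sum(arma::square(A), 1);
  arma::vec sb = arma::sum(arma::square(B), 1);
  arma::mat D = arma::repmat(sa, 1, B.n_rows) + arma::repmat(sb.t(), A.n_rows, 1)
                - 2.0 * (A * B.t());
  return arma::exp(-gamma * arma::clamp(D, 0.0, arma::datum::inf));
}
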