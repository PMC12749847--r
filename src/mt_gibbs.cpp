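// Gibbs sampler for multi-trait GBLUP with Kronecker covariance:
//   Y (n x q), y_j = mu_j + u_j + e_j,
//   vec(U) ~ MVN(0, K (x) G),  rows of E ~ MVN(0, R).
// G enters through its eigendecomposition G = V diag(d) V' (d > 0 after
// clipping), so the genetic-value update factorizes over eigenvectors:
// row i of Ut = V'U has full conditional precision K^{-1}/d_i + R^{-1}.
// Missing/masked cells are handled by data augmentation. All random numbers
// come from R's RNG, so set.seed() in R makes chains reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat sym(const mat& A) { return (A + A.t()) / 2.0; }

static vec rnorm_vec(int k) {
  vec z(k);
  for (int i = 0; i < k; i++) z(i) = R::norm_rand();
  return z;
}

// Wishart draw via the Bartlett decomposition; S is the scale matrix.
static mat rwishart(double df, const mat& S) {
  int q = S.n_rows;
  mat L = chol(sym(S), "lower");
  mat A(q, q, fill::zeros);
  for (int i = 0; i < q; i++) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; j++) A(i, j) = R::norm_rand();
  }
  mat LA = L * A;
  return LA * LA.t();
}

static mat riwishart(double df, const mat& Psi) {
  return sym(inv_sympd(sym(rwishart(df, inv_sympd(sym(Psi))))));
}

// Sample x ~ N(P^{-1} b, P^{-1}) given precision P and shift b.
static vec rmvnorm_prec(const mat& P, const vec& b) {
  mat U = chol(sym(P));            // upper: P = U'U
  vec mu = solve(sym(P), b);
  return mu + solve(trimatu(U), rnorm_vec(b.n_elem));
}

// [[Rcpp::export]]
Rcpp::List mt_gibbs_cpp(const arma::mat& Y, const arma::umat& obs,
                        const arma::mat& V, const arma::vec& d,
                        const arma::mat& SK0, double nuK,
                        const arma::mat& SR0, double nuR,
                        int n_iter, int burnin, int thin) {
  const int n = Y.n_rows, q = Y.n_cols;
  Rcpp::RNGScope scope;

  // initial values: intercept = observed column means, K = R = half the
  // prior scale's implied covariance, U = 0, missing cells at the intercept
  rowvec mu(q);
  for (int j = 0; j < q; j++) {
    uvec oj = find(obs.col(j) == 1);
    mu(j) = oj.n_elem ? mean(Y.elem(oj + (uword)j * n)) : 0.0;
  }
  mat K = SK0 / std::max(nuK - q - 1.0, 1.0);
  mat R = SR0 / std::max(nuR - q - 1.0, 1.0);
  mat Yc = Y;
  for (int i = 0; i < n; i++)
    for (int j = 0; j < q; j++)
      if (!obs(i, j)) Yc(i, j) = mu(j);
  mat U(n, q, fill::zeros), Ut(n, q, fill::zeros);
  vec dinv = 1.0 / d;

  // rows with at least one unobserved cell (visited every iteration)
  std::vector<int> miss_rows;
  for (int i = 0; i < n; i++) if (any(obs.row(i) == 0)) miss_rows.push_back(i);

  const int n_save = (n_iter - burnin + thin - 1) / thin;
  mat Ksum(q, q, fill::zeros), K2sum(q, q, fill::zeros);
  mat Rsum(q, q, fill::zeros), R2sum(q, q, fill::zeros);
  mat predsum(n, q, fill::zeros), pred2sum(n, q, fill::zeros);
  rowvec musum(q, fill::zeros);
  mat h2_samples(n_save, q);
  const int noff = q * (q - 1) / 2;
  mat rg_samples(n_save, std::max(noff, 1));
  int saved = 0;

  for (int it = 0; it < n_iter; it++) {
    // (1) impute unobserved cells from their conditional normal given the
    // observed traits of the same line (residual covariance R)
    for (size_t k = 0; k < miss_rows.size(); k++) {
      int i = miss_rows[k];
      uvec m = find(obs.row(i).t() == 0);
      uvec o = find(obs.row(i).t() == 1);
      vec yi = Y.row(i).t(), ui = U.row(i).t(), muv = mu.t();
      vec mean_m = muv.elem(m) + ui.elem(m);
      mat cov_m;
      if (o.n_elem) {
        mat Roo = R.submat(o, o), Rmo = R.submat(m, o);
        vec resid_o = yi.elem(o) - muv.elem(o) - ui.elem(o);
        mat RooInv_Rom = solve(sym(Roo), Rmo.t());
        mean_m += RooInv_Rom.t() * resid_o;
        cov_m = R.submat(m, m) - Rmo * RooInv_Rom;
      } else {
        cov_m = R.submat(m, m);
      }
      mat Lc = chol(sym(cov_m) + 1e-12 * eye(m.n_elem, m.n_elem), "lower");
      vec draw = mean_m + Lc * rnorm_vec(m.n_elem);
      for (uword t = 0; t < m.n_elem; t++) Yc(i, m(t)) = draw(t);
    }

    // (2) genetic values in the eigenbasis, row by row
    mat Kinv = inv_sympd(sym(K));
    mat Rinv = inv_sympd(sym(R));
    mat Et = V.t() * (Yc - repmat(mu, n, 1));
    for (int i = 0; i < n; i++) {
      mat P = Kinv * dinv(i) + Rinv;
      vec b = Rinv * Et.row(i).t();
      Ut.row(i) = rmvnorm_prec(P, b).t();
    }
    U = V * Ut;

    // (3) trait covariances from inverse-Wishart full conditionals
    mat SK = Ut.t() * (Ut.each_col() % dinv) + SK0;
    K = riwishart(nuK + n, SK);
    mat E = Yc - repmat(mu, n, 1) - U;
    mat SR = E.t() * E + SR0;
    R = riwishart(nuR + n, SR);

    // (4) intercepts: mu | . ~ N(colmeans(Yc - U), R / n)
    rowvec mbar = mean(Yc - U, 0);
    mat Lr = chol(sym(R) / n, "lower");
    mu = mbar + (Lr * rnorm_vec(q)).t();

    if (it >= burnin && (it - burnin) % thin == 0) {
      Ksum += K; K2sum += K % K;
      Rsum += R; R2sum += R % R;
      mat pred = repmat(mu, n, 1) + U;
      predsum += pred; pred2sum += pred % pred;
      musum += mu;
      for (int j = 0; j < q; j++)
        h2_samples(saved, j) = K(j, j) / (K(j, j) + R(j, j));
      int c = 0;
      for (int a = 0; a < q; a++)
        for (int b2 = a + 1; b2 < q; b2++)
          rg_samples(saved, c++) = K(a, b2) / std::sqrt(K(a, a) * K(b2, b2));
      saved++;
    }
  }

  double ns = (double)saved;
  auto sd_of = [&](const mat& s, const mat& s2) {
    mat v = (s2 - (s % s) / ns) / std::max(ns - 1.0, 1.0);
    return sqrt(clamp(v, 0.0, datum::inf));
  };
  return Rcpp::List::create(
    Rcpp::Named("K_mean") = Ksum / ns,
    Rcpp::Named("K_sd") = sd_of(Ksum, K2sum),
    Rcpp::Named("R_mean") = Rsum / ns,
    Rcpp::Named("R_sd") = sd_of(Rsum, R2sum),
    Rcpp::Named("pred_mean") = predsum / ns,
    Rcpp::Named("pred_sd") = sd_of(predsum, pred2sum),
    Rcpp::Named("mu_mean") = musum / ns,
    Rcpp::Named("h2_samples") = h2_samples.rows(0, saved - 1),
    Rcpp::Named("rg_samples") =
      (noff > 0) ? rg_samples.rows(0, saved - 1) : mat(saved, 0),
    Rcpp::Named("n_saved") = saved);
}
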