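// Graphical lasso via block coordinate descent (Friedman-style), with the
// l1 penalty applied to off-diagonal precision entries only, so that the
// diagonal of the working covariance W stays fixed at diag(S).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One full optimization at penalty lam. W and B are warm starts, updated in
// place: W is the working covariance estimate (inverse of Theta at
// convergence), B holds the per-column lasso coefficients (B(i, j) = coef of
// variable i in the regression defining column j; B(j, j) unused, kept 0).
static int glasso_bcd(const mat& S, double lam, mat& W, mat& B,
                      int maxit, double tol,
                      int inner_maxit, double inner_tol) {
  const int p = S.n_rows;
  if (p == 1) { W = S; return 0; }
  uvec all = regspace<uvec>(0, p - 1);
  int it = 0;
  for (; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx = find(all != (unsigned) j);
      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec b = B.col(j);
      b = b.elem(idx);
      // lasso: minimize 0.5 b'W11 b - s12'b + lam ||b||_1
      for (int in = 0; in < inner_maxit; ++in) {
        double del = 0.0;
        for (int i = 0; i < p - 1; ++i) {
          const double bi_old = b(i);
          const double r = s12(i) - dot(W11.row(i), b) + W11(i, i) * bi_old;
          const double bi = soft(r, lam) / W11(i, i);
          if (bi != bi_old) {
            b(i) = bi;
            const double d = std::fabs(bi - bi_old);
            if (d > del) del = d;
          }
        }
        if (del < inner_tol) break;
      }
      vec w12 = W11 * b;
      int k = 0;
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        const double d = std::fabs(W(i, j) - w12(k));
        if (d > maxdiff) maxdiff = d;
        W(i, j) = w12(k);
        W(j, i) = w12(k);
        B(i, j) = b(k);
        ++k;
      }
    }
    if (maxdiff < tol) { ++it; break; }
  }
  return it;
}

// Recover the precision matrix from (W, B); exact zeros in B give exact
// zeros in Theta, and coefficients below solver resolution are treated as
// zero. Symmetrized by averaging, keeping the zero pattern.
static mat recover_theta(const mat& W, const mat& B) {
  const int p = W.n_rows;
  const double zero_tol = 1e-10;
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    double quad = 0.0;
    for (int i = 0; i < p; ++i)
      if (i != j) quad += B(i, j) * W(i, j);
    const double t22 = 1.0 / (W(j, j) - quad);
    Theta(j, j) = t22;
    for (int i = 0; i < p; ++i)
      if (i != j && std::fabs(B(i, j)) > zero_tol)
        Theta(i, j) = -B(i, j) * t22;
  }
  mat Ts(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    Ts(j, j) = Theta(j, j);
    for (int i = 0; i < j; ++i) {
      if (Theta(i, j) == 0.0 && Theta(j, i) == 0.0) continue;
      const double v = 0.5 * (Theta(i, j) + Theta(j, i));
      Ts(i, j) = v;
      Ts(j, i) = v;
    }
  }
  return Ts;
}

// [[Rcpp::export]]
List glasso_cpp(const arma::mat& S, double lam,
                Rcpp::Nullable<Rcpp::NumericMatrix> W0 = R_NilValue,
                Rcpp::Nullable<Rcpp::NumericMatrix> B0 = R_NilValue,
                int maxit = 500, double tol = 1e-9,
                int inner_maxit = 2000, double inner_tol = 1e-11) {
  const int p = S.n_rows;
  mat W = W0.isNotNull() ? as<mat>(W0.get()) : mat(S);
  mat B = B0.isNotNull() ? as<mat>(B0.get()) : mat(p, p, fill::zeros);
  W.diag() = S.diag();  // unpenalized diagonal
  const int it = glasso_bcd(S, lam, W, B, maxit, tol, inner_maxit, inner_tol);
  mat Theta = recover_theta(W, B);
  return List::create(_["Theta"] = Theta, _["W"] = W, _["B"] = B,
                      _["iterations"] = it);
}

// Unpenalized MLE restricted to a fixed support: block coordinate descent
// with zero penalty, updating only coordinates inside the support (all
// others stay structurally zero). Used for the EBIC likelihood refit.
// [[Rcpp::export]]
List glasso_restricted_cpp(const arma::mat& S, const arma::umat& support,
                           int maxit = 500, double tol = 1e-9,
                           int inner_maxit = 2000, double inner_tol = 1e-11) {
  const int p = S.n_rows;
  mat W(S), B(p, p, fill::zeros);
  uvec all = regspace<uvec>(0, p - 1);
  int it = 0;
  for (; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx = find(all != (unsigned) j);
      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec b = B.col(j);
      b = b.elem(idx);
      uvec free(p - 1);
      int k = 0;
      for (int i = 0; i < p; ++i)
        if (i != j) free(k++) = support(i, j) ? 1 : 0;
      for (int in = 0; in < inner_maxit; ++in) {
        double del = 0.0;
        for (int i = 0; i < p - 1; ++i) {
          if (!free(i)) continue;
          const double bi_old = b(i);
          const double r = s12(i) - dot(W11.row(i), b) + W11(i, i) * bi_old;
          const double bi = r / W11(i, i);
          if (bi != bi_old) {
            b(i) = bi;
            const double d = std::fabs(bi - bi_old);
            if (d > del) del = d;
          }
        }
        if (del < inner_tol) break;
      }
      vec w12 = W11 * b;
      k = 0;
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        const double d = std::fabs(W(i, j) - w12(k));
        if (d > maxdiff) maxdiff = d;
        W(i, j) = w12(k);
        W(j, i) = w12(k);
        B(i, j) = b(k);
        ++k;
      }
    }
    if (maxdiff < tol) { ++it; break; }
  }
  mat Theta = recover_theta(W, B);
  return List::create(_["Theta"] = Theta, _["W"] = W,
                      _["iterations"] = it);
}

// [[Rcpp::export]]
List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                     int maxit = 500, double tol = 1e-9,
                     int inner_maxit = 2000, double inner_tol = 1e-11) {
  const int p = S.n_rows;
  const int nl = lambdas.n_elem;
  mat W(S), B(p, p, fill::zeros);
  cube Thetas(p, p, nl);
  IntegerVector iters(nl);
  for (int l = 0; l < nl; ++l) {  // warm starts down the path
    iters[l] = glasso_bcd(S, lambdas(l), W, B, maxit, tol,
                          inner_maxit, inner_tol);
    Thetas.slice(l) = recover_theta(W, B);
  }
  return List::create(_["Thetas"] = Thetas, _["iterations"] = iters);
}
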