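// Per-gene LASSO with fold-wise cross-validation, sharing Gram matrices
// across genes and folds.  The transition-matrix step solves p_g
// independent problems
//   (1/2n)||g_j - a_j - R theta||^2 + lambda |theta|_1
// over the same regulator matrix R, so R'R/n (full data and per training
// fold) is computed once and every per-gene path is coordinate descent on
// covariance updates.  Inputs are expected column-centered; intercepts
// are recovered by the caller from column means.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double softt(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// lasso path on Gram quantities: A = X'X/n (diagonal diag), c = X'y/n.
// beta is warm-started / overwritten per lambda; out has one column per
// lambda value (descending).
static void cd_lasso_path(const mat& A, const vec& c, const vec& lambdas,
                          double thresh, int maxit, mat& out) {
  const int p = A.n_rows;
  vec beta(p, fill::zeros);
  vec s(p, fill::zeros);          // s = A * beta, maintained incrementally
  std::vector<int> active;
  active.reserve(p);
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  for (uword li = 0; li < lambdas.n_elem; ++li) {
    const double lam = lambdas(li);
    auto sweep = [&](const std::vector<int>& idx) -> double {
      double maxdel = 0.0;
      for (int j : idx) {
        const double ajj = A(j, j);
        if (ajj <= 0) continue;
        const double z = c(j) - s(j) + ajj * beta(j);
        const double bn = softt(z, lam) / ajj;
        const double del = bn - beta(j);
        if (del != 0.0) {
          beta(j) = bn;
          s += A.col(j) * del;
          const double ad = std::abs(del);
          if (ad > maxdel) maxdel = ad;
        }
      }
      return maxdel;
    };
    // alternate full sweeps (which can grow the active set) with
    // active-set-only iteration until a full sweep is quiet
    for (int outer = 0; outer < maxit; ++outer) {
      const double d_full = sweep(all);
      if (d_full < thresh) break;
      active.clear();
      for (int j = 0; j < p; ++j) if (beta(j) != 0.0) active.push_back(j);
      for (int it = 0; it < maxit; ++it) {
        if (sweep(active) < thresh) break;
      }
    }
    out.col(li) = beta;
  }
}

// [[Rcpp::export]]
Rcpp::List gram_lasso_cv_cpp(const arma::mat& R, const arma::mat& G,
                             const arma::ivec& foldid, int nlambda,
                             double min_ratio, double thresh, int maxit) {
  const int n = R.n_rows, p = R.n_cols, pg = G.n_cols;
  const int nfold = foldid.max();

  mat A_full = R.t() * R / n;
  std::vector<mat> A_tr(nfold);
  std::vector<uvec> tr_idx(nfold), te_idx(nfold);
  for (int f = 0; f < nfold; ++f) {
    tr_idx[f] = find(foldid != f + 1);
    te_idx[f] = find(foldid == f + 1);
    const mat Rtr = R.rows(tr_idx[f]);
    A_tr[f] = Rtr.t() * Rtr / Rtr.n_rows;
  }

  mat Theta(p, pg, fill::zeros);
  vec chosen(pg);
  mat path(p, nlambda);

  for (int j = 0; j < pg; ++j) {
    const vec g = G.col(j);
    const vec c_full = R.t() * g / n;
    const double lmax = std::max(abs(c_full).max(), 1e-12);
    vec lambdas = exp(linspace(std::log(lmax),
                               std::log(lmax * min_ratio), nlambda));
    const double tol_j = thresh * lmax;   // scale-relative convergence
    vec cverr(nlambda, fill::zeros);
    for (int f = 0; f < nfold; ++f) {
      const mat Rtr = R.rows(tr_idx[f]);
      const vec gtr = g.elem(tr_idx[f]);
      const vec c_tr = Rtr.t() * gtr / Rtr.n_rows;
      cd_lasso_path(A_tr[f], c_tr, lambdas, tol_j, maxit, path);
      const mat pred = R.rows(te_idx[f]) * path;
      const vec gte = g.elem(te_idx[f]);
      for (int li = 0; li < nlambda; ++li) {
        const vec r = gte - pred.col(li);
        cverr(li) += dot(r, r);
      }
    }
    uword best;
    cverr.min(best);
    // refit on the full data down to the selected lambda
    vec lam_seq = lambdas.head(best + 1);
    mat full_path(p, best + 1);
    cd_lasso_path(A_full, c_full, lam_seq, tol_j, maxit, full_path);
    Theta.col(j) = full_path.col(best);
    chosen(j) = lambdas(best);
  }
  return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("lambda") = chosen);
}

// Single fixed-lambda fits for all genes on the full Gram (used by the
// fixed-penalty mode).
// [[Rcpp::export]]
arma::mat gram_lasso_fixed_cpp(const arma::mat& R, const arma::mat& G,
                               double lambda, double thresh, int maxit) {
  const int n = R.n_rows, p = R.n_cols, pg = G.n_cols;
  mat A = R.t() * R / n;
  mat Theta(p, pg);
  mat out(p, 1);
  vec lamv(1);
  lamv(0) = lambda;
  for (int j = 0; j < pg; ++j) {
    const vec c = R.t() * G.col(j) / n;
    const double tol_j = thresh * std::max(abs(c).max(), 1e-12);
    cd_lasso_path(A, c, lamv, tol_j, maxit, out);
    Theta.col(j) = out.col(0);
  }
  return Theta;
}
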