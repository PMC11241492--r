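// Recursive feature elimination path with cross-validated predictions,
// ridge estimator.
//
// Works in the dual: for ridge with penalty lambda on the squared-error
// loss, beta = X' (X X' + lambda I)^{-1} y exactly (any n, p; lambda > 0),
// so the whole elimination path runs on the n x n gram matrix.  X arrives
// standardized (zero column means), hence the gram needs no centering.
//
// Out-of-fold predictions use the exact block cross-validation identity for
// penalized-least-squares smoothers: with hat matrix H (here
// I - H = lambda * Ainv * C, where Ainv = (K + lambda I)^{-1} and
// C = I - 11'/n is the centering projector of the unpenalized intercept),
// the predictions of fold F from a model fitted without fold F are
//   pred_F = y_F - [(I - H)_{FF}]^{-1} ((I - H) y)_F,
// and (I - H) y = lambda * Ainv * (y - mean(y)) is the full-fit dual
// solution already needed for the elimination coefficients.  Each round
// therefore costs one maintained-inverse refresh, two matrix-vector
// products and k tiny |F| x |F| solves.
//
// Dropping `step` features is a rank-`step` downdate of the gram, so Ainv
// is maintained by Sherman-Morrison-Woodbury updates at O(n^2 step) per
// round instead of refactorizing at O(n^3); it is refreshed from the
// explicitly maintained (exact) gram periodically so accumulated
// floating-point drift stays negligible.
//
// The routine returns, for every visited feature count, the out-of-fold CV
// predictions plus the elimination order.  Scoring the path under any
// criterion, and truncating it at any floor at or above `min_features`, is
// done by the caller: within each round features are dropped in increasing
// |coefficient| order, so the survivors at any intermediate count are
// exactly the complement of a prefix of the elimination order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int REFRESH_EVERY = 64;

// SMW update of Ainv for A_new = A - U U' (U: n x s):
// Ainv += (Ainv U) (I - U' Ainv U)^{-1} (Ainv U)'.
static void smw_downdate(mat& Ainv, const mat& U) {
  mat V = Ainv * U;
  mat S = eye(U.n_cols, U.n_cols) - U.t() * V;
  mat M = solve(S, V.t(), solve_opts::likely_sympd);
  Ainv += V * M;
}

// [[Rcpp::export]]
Rcpp::List rfecv_path_cpp(const arma::mat& X, const arma::vec& y,
                          const arma::ivec& fold, double lambda,
                          int step, int min_features) {
  const int n = (int)X.n_rows;
  const int p = (int)X.n_cols;
  if ((int)y.n_elem != n) Rcpp::stop("X and y sizes disagree");
  if (step < 1) Rcpp::stop("step must be >= 1");
  if (p < min_features) Rcpp::stop("fewer features than min_features");
  if (min_features < 1) Rcpp::stop("min_features must be >= 1");

  const int k = fold.max();
  std::vector<uvec> te_sets(k);
  for (int f = 1; f <= k; ++f) {
    te_sets[f - 1] = find(fold == f);
    if (te_sets[f - 1].n_elem == 0) Rcpp::stop("empty CV fold");
  }

  mat Af = X * X.t();
  Af.diag() += lambda;
  mat Afinv = inv_sympd(Af);
  vec y_c = y - mean(y);
  const vec ones_n(n, fill::ones);

  // Working copy with active columns kept contiguous at the front; dropped
  // columns are swapped to the back so the coefficient computation is one
  // contiguous gemv.
  mat Xw = X;
  std::vector<int> orig(p);
  for (int j = 0; j < p; ++j) orig[j] = j;
  int na = p;

  const int n_rounds = (p - min_features + step - 1) / step + 1;
  mat preds(n, n_rounds);
  std::vector<int> counts;
  counts.reserve(n_rounds);
  std::vector<int> elim_order;
  elim_order.reserve(p - min_features);
  int rounds_since_refresh = 0;
  int col = 0;

  while (true) {
    counts.push_back(na);
    vec a_full = Afinv * y_c;          // (I - H) y = lambda * a_full
    vec r = Afinv * ones_n;
    for (int f = 0; f < k; ++f) {
      const uvec& te = te_sets[f];
      mat M = Afinv.submat(te, te);
      M.each_col() -= r.elem(te) / (double)n;
      vec pr = y.elem(te) - solve(M, a_full.elem(te));  // lambda cancels
      for (uword i = 0; i < te.n_elem; ++i) preds(te[i], col) = pr[i];
    }
    ++col;
    if (na <= min_features) break;

    vec beta = Xw.cols(0, na - 1).t() * a_full;

    const int s = std::min(step, na - min_features);
    std::vector<int> ord(na);
    for (int i = 0; i < na; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(), [&](int a1, int a2) {
      double b1 = std::abs(beta[a1]), b2 = std::abs(beta[a2]);
      if (b1 != b2) return b1 < b2;
      return orig[a1] < orig[a2];
    });
    mat Xd(n, s);
    for (int i = 0; i < s; ++i) {
      Xd.col(i) = Xw.col(ord[i]);
      elim_order.push_back(orig[ord[i]] + 1);  // 1-based for R
    }
    // swap dropped columns out of the active block (largest position first)
    std::vector<int> loc(ord.begin(), ord.begin() + s);
    std::sort(loc.begin(), loc.end(), std::greater<int>());
    for (int l : loc) {
      if (l != na - 1) {
        Xw.swap_cols(l, na - 1);
        std::swap(orig[l], orig[na - 1]);
      }
      --na;
    }

    Af -= Xd * Xd.t();
    if (++rounds_since_refresh >= REFRESH_EVERY) {
      Afinv = inv_sympd(Af);
      rounds_since_refresh = 0;
    } else {
      smw_downdate(Afinv, Xd);
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("counts") = counts,
    Rcpp::Named("elim_order") = elim_order,
    Rcpp::Named("preds") = preds.cols(0, col - 1));
}
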