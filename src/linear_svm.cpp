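#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Dual SMO solver for the two-class linear soft-margin SVM:
//   min_alpha  1/2 sum_ij alpha_i alpha_j y_i y_j K_ij - sum_i alpha_i
//   s.t.       0 <= alpha_i <= C,  sum_i alpha_i y_i = 0
// Pair selection is the maximal-violating-pair rule; the offset is recovered
// with the usual free-support-vector average (midpoint of the feasibility
// interval when no alpha is strictly inside the box).

struct SmoResult {
  arma::vec alpha;
  double rho;
  int iter;
};

static SmoResult smo_solve(const arma::mat& K, const arma::vec& y,
                           double C, double tol, int max_iter,
                           const arma::vec* warm = nullptr) {
  const int n = K.n_rows;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec G(n);
  if (warm != nullptr) {
    alpha = *warm;                      // feasible start from a related problem
    G = y % (K * (alpha % y)) - 1.0;
  } else {
    G.fill(-1.0);
  }
  const double inf = std::numeric_limits<double>::infinity();

  int it = 0;
  for (; it < max_iter; ++it) {
    double Gmax = -inf, Gmin = inf;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > Gmax)  { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < tol) break;

    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;
    double step = -(y[i] * G[i] - y[j] * G[j]) / quad;

    // keep alpha_i + y_i*step and alpha_j - y_j*step inside [0, C]
    double lo = -inf, hi = inf;
    if (y[i] > 0) { lo = std::max(lo, -alpha[i]);    hi = std::min(hi, C - alpha[i]); }
    else          { lo = std::max(lo, alpha[i] - C); hi = std::min(hi, alpha[i]); }
    if (y[j] > 0) { lo = std::max(lo, alpha[j] - C); hi = std::min(hi, alpha[j]); }
    else          { lo = std::max(lo, -alpha[j]);    hi = std::min(hi, C - alpha[j]); }
    if (step < lo) step = lo;
    if (step > hi) step = hi;
    if (step == 0.0) break;

    const double dai =  y[i] * step;
    const double daj = -y[j] * step;
    alpha[i] += dai;
    alpha[j] += daj;
    G += y % (K.col(i) * (y[i] * dai) + K.col(j) * (y[j] * daj));
  }

  // offset: average y_t G_t over free SVs, else midpoint of the KKT interval
  double ub = inf, lb = -inf, sum_free = 0.0;
  int n_free = 0;
  const double eps = 1e-12 * std::max(1.0, C);
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C - eps) {          // at upper bound
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= eps) {       // at lower bound
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++n_free;
      sum_free += yG;
    }
  }
  SmoResult res;
  res.alpha = alpha;
  res.rho = (n_free > 0) ? sum_free / n_free : (ub + lb) / 2.0;
  res.iter = it;
  return res;
}

// ascending relevance order of 0-based feature indices: least |w| first,
// ties broken by ascending index (stable)
static std::vector<int> rank_ascending(const arma::vec& w) {
  std::vector<int> idx(w.n_elem);
  for (size_t k = 0; k < w.n_elem; ++k) idx[k] = (int)k;
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    return std::abs(w[a]) < std::abs(w[b]);
  });
  return idx;
}

static inline int predict_sign(const arma::vec& w, double b, const arma::vec& x) {
  const double d = arma::dot(w, x) + b;
  return (d >= 0) ? 1 : -1;  // decision exactly 0 -> positive class
}

// [[Rcpp::export(name = ".svm_train_cpp")]]
List svm_train_cpp(const arma::mat& X, const arma::vec& y,
                   double cost, double tol, int max_iter) {
  arma::mat K = X * X.t();
  SmoResult s = smo_solve(K, y, cost, tol, max_iter);
  arma::vec w = X.t() * (s.alpha % y);
  return List::create(_["w"] = w,
                      _["b"] = -s.rho,
                      _["alpha"] = s.alpha,
                      _["iterations"] = s.iter);
}

// Inner-fold elimination path: train on (X, y), predict the held-out feature
// vector xnew at every feature count p-1 .. 1 and at the full count p.
// rerank = FALSE follows the fixed ranking computed once from the full model;
// rerank = TRUE recomputes the ranking from the current model after each
// elimination (classic recursive feature elimination).
// The Gram matrix is downdated (K -= x_j x_j^T) as features are removed and
// each solve warm-starts from the previous alpha: the optimum is unchanged
// (the dual is convex) but convergence is much faster along the path.
// [[Rcpp::export(name = ".rfe_path_cpp")]]
List rfe_path_cpp(const arma::mat& X, const arma::vec& y, const arma::vec& xnew,
                  double cost, double tol, int max_iter, bool rerank) {
  const int p = X.n_cols;
  arma::mat K = X * X.t();
  SmoResult s = smo_solve(K, y, cost, tol, max_iter);
  arma::vec w = X.t() * (s.alpha % y);
  double b = -s.rho;
  const int pred_full = predict_sign(w, b, xnew);

  IntegerVector preds(std::max(p - 1, 0));
  std::vector<int> active(p);
  for (int k = 0; k < p; ++k) active[k] = k;
  std::vector<int> fixed_order;          // ascending relevance over original indices
  if (!rerank) fixed_order = rank_ascending(w);
  size_t n_removed = 0;

  for (int c = p - 1; c >= 1; --c) {
    int drop;                            // original index of the least relevant feature
    if (rerank) {
      // w is aligned with `active`; least |w|, tie -> smallest original index
      int pos = 0;
      for (size_t k = 1; k < active.size(); ++k) {
        const double a = std::abs(w[k]), best = std::abs(w[pos]);
        if (a < best || (a == best && active[k] < active[pos])) pos = (int)k;
      }
      drop = active[pos];
      active.erase(active.begin() + pos);
    } else {
      drop = fixed_order[n_removed++];
      active.erase(std::find(active.begin(), active.end(), drop));
    }
    K -= X.col(drop) * X.col(drop).t();
    s = smo_solve(K, y, cost, tol, max_iter, &s.alpha);
    arma::uvec cols(active.size());
    for (size_t k = 0; k < active.size(); ++k) cols[k] = (arma::uword)active[k];
    w = X.cols(cols).t() * (s.alpha % y);
    b = -s.rho;
    preds[c - 1] = predict_sign(w, b, xnew.elem(cols));
  }
  return List::create(_["preds"] = preds, _["pred_full"] = pred_full);
}

// Outer-fold selection: choose the q most discriminant features of (X, y)
// under the same ranking schedule as the inner loop, then train the final
// model on that subset. Returns 1-based selected indices ordered most
// discriminant first, the final (w, b), and the full-model weights.
// [[Rcpp::export(name = ".rfe_select_cpp")]]
List rfe_select_cpp(const arma::mat& X, const arma::vec& y,
                    double cost, double tol, int max_iter,
                    bool rerank, int q) {
  const int p = X.n_cols;
  arma::mat K = X * X.t();
  SmoResult s = smo_solve(K, y, cost, tol, max_iter);
  arma::vec w = X.t() * (s.alpha % y);
  double b = -s.rho;
  arma::vec w_full = w;

  std::vector<int> active(p);
  for (int k = 0; k < p; ++k) active[k] = k;

  if (!rerank) {
    std::vector<int> ord = rank_ascending(w);   // ascending relevance
    std::vector<int> keep(ord.end() - q, ord.end());
    std::reverse(keep.begin(), keep.end());     // most discriminant first
    active = keep;
    arma::uvec cols(active.size());
    for (size_t k = 0; k < active.size(); ++k) cols[k] = (arma::uword)active[k];
    arma::mat Xs = X.cols(cols);
    K = Xs * Xs.t();
    s = smo_solve(K, y, cost, tol, max_iter, &s.alpha);
    w = Xs.t() * (s.alpha % y);
    b = -s.rho;
  } else {
    while ((int)active.size() > q) {
      int pos = 0;
      for (size_t k = 1; k < active.size(); ++k) {
        const double a = std::abs(w[k]), best = std::abs(w[pos]);
        if (a < best || (a == best && active[k] < active[pos])) pos = (int)k;
      }
      const int drop = active[pos];
      active.erase(active.begin() + pos);
      K -= X.col(drop) * X.col(drop).t();
      s = smo_solve(K, y, cost, tol, max_iter, &s.alpha);
      arma::uvec cols(active.size());
      for (size_t k = 0; k < active.size(); ++k) cols[k] = (arma::uword)active[k];
      w = X.cols(cols).t() * (s.alpha % y);
      b = -s.rho;
    }
  }

  if (rerank) {
    // order surviving features by final-model relevance, most discriminant first
    std::vector<int> ord = rank_ascending(w);
    IntegerVector selected(ord.size());
    NumericVector w_out(ord.size());
    for (size_t k = 0; k < ord.size(); ++k) {
      const int src = ord[ord.size() - 1 - k];
      selected[k] = active[src] + 1;
      w_out[k] = w[src];
    }
    return List::create(_["selected"] = selected, _["w"] = w_out, _["b"] = b,
                        _["w_full"] = w_full);
  }

  IntegerVector selected(active.size());
  NumericVector w_out(active.size());
  for (size_t k = 0; k < active.size(); ++k) {
    selected[k] = active[k] + 1;
    w_out[k] = w[k];
  }
  return List::create(_["selected"] = selected, _["w"] = w_out, _["b"] = b,
                      _["w_full"] = w_full);
}
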