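// Forward pass of the adaptive regression spline engine.
//
// Starting from the intercept, each step screens every (parent basis,
// variable, knot) candidate and adds the mirrored hinge pair whose joint OLS
// fit most reduces the residual sum of squares. An orthonormal basis Q of the
// current design is maintained so each candidate's RSS reduction is the
// projection of the residual onto the residualised candidate pair (exact,
// no refit needed during screening). Coefficients are refit by OLS in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Factor {
  int var;      // 0-based column of X
  double knot;
  int dir;      // +1: max(0, x - t); -1: max(0, t - x)
};

arma::vec basis_column(const arma::mat& X, const std::vector<Factor>& fs) {
  arma::vec b(X.n_rows, arma::fill::ones);
  for (size_t i = 0; i < fs.size(); ++i) {
    arma::vec v = X.col(fs[i].var) - fs[i].knot;
    if (fs[i].dir < 0) v = -v;
    b %= arma::clamp(v, 0.0, arma::datum::inf);
  }
  return b;
}

bool parent_uses_var(const std::vector<Factor>& fs, int v) {
  for (size_t i = 0; i < fs.size(); ++i)
    if (fs[i].var == v) return true;
  return false;
}

}  // namespace

// [[Rcpp::export]]
List cpp_mars_forward(const arma::mat& X, const arma::vec& y, int max_terms,
                      int max_degree, double thresh,
                      const List& knot_candidates) {
  const arma::uword n = X.n_rows;
  const int p = (int)X.n_cols;

  std::vector<std::vector<Factor> > bases;
  bases.push_back(std::vector<Factor>());  // intercept

  arma::mat Q(n, 1);
  Q.col(0).fill(1.0 / std::sqrt((double)n));
  arma::vec yres = y - Q * (Q.t() * y);
  double rss = arma::dot(yres, yres);
  const double eps = 1e-10 * std::max(1.0, arma::dot(y, y));
  bool stopped_degenerate = false;

  std::vector<arma::vec> knots(p);
  for (int v = 0; v < p; ++v) knots[v] = as<arma::vec>(knot_candidates[v]);

  while ((int)bases.size() < max_terms) {
    double best_gain = -1.0;
    int best_parent = -1, best_var = -1, best_forms = 0;
    double best_knot = 0.0;

    for (int pa = 0; pa < (int)bases.size(); ++pa) {
      if ((int)bases[pa].size() >= max_degree) continue;
      arma::vec bp = basis_column(X, bases[pa]);
      if (arma::dot(bp, bp) < 1e-12) continue;
      for (int v = 0; v < p; ++v) {
        if (parent_uses_var(bases[pa], v)) continue;
        const arma::vec& kv = knots[v];
        const arma::vec xv = X.col(v);
        const int K = (int)kv.n_elem;
        if (K == 0) continue;
        arma::mat H(n, 2 * K);
        for (int t = 0; t < K; ++t) {
          arma::vec d = xv - kv[t];
          H.col(2 * t) = bp % arma::clamp(d, 0.0, arma::datum::inf);
          H.col(2 * t + 1) = bp % arma::clamp(-d, 0.0, arma::datum::inf);
        }
        arma::mat R = H - Q * (Q.t() * H);
        arma::vec rty = R.t() * yres;
        for (int t = 0; t < K; ++t) {
          const arma::vec& r1 = R.unsafe_col(2 * t);
          const arma::vec& r2 = R.unsafe_col(2 * t + 1);
          double g11 = arma::dot(r1, r1), g22 = arma::dot(r2, r2),
                 g12 = arma::dot(r1, r2);
          double b1 = rty[2 * t], b2 = rty[2 * t + 1];
          double gain = -1.0;
          int forms = 0;
          double det = g11 * g22 - g12 * g12;
          if (g11 > eps && g22 > eps && det > 1e-10 * g11 * g22) {
            gain = (g22 * b1 * b1 - 2.0 * g12 * b1 * b2 + g11 * b2 * b2) / det;
            forms = 3;  // both hinges informative
          } else if (g11 > eps) {
            gain = b1 * b1 / g11;
            forms = 1;  // upward hinge only
          } else if (g22 > eps) {
            gain = b2 * b2 / g22;
            forms = 2;  // downward hinge only
          }
          if (gain > best_gain) {
            best_gain = gain;
            best_parent = pa;
            best_var = v;
            best_knot = kv[t];
            best_forms = forms;
          }
        }
      }
    }

    if (best_parent < 0) { stopped_degenerate = true; break; }
    if (rss <= 0 || best_gain / std::max(rss, 1e-300) < thresh) break;

    // append the winning pair (or the single non-degenerate member)
    arma::vec bp = basis_column(X, bases[best_parent]);
    for (int form = 0; form < 2; ++form) {
      if (!(best_forms & (1 << form))) continue;
      if ((int)bases.size() >= max_terms && form == 1) break;
      std::vector<Factor> fs = bases[best_parent];
      Factor f;
      f.var = best_var;
      f.knot = best_knot;
      f.dir = (form == 0) ? 1 : -1;
      fs.push_back(f);
      arma::vec c = basis_column(X, fs);
      // residualise against current Q (twice, for numerical stability)
      arma::vec r = c - Q * (Q.t() * c);
      r -= Q * (Q.t() * r);
      double nr = arma::norm(r);
      if (nr * nr < 1e-12 * std::max(1.0, arma::dot(c, c))) continue;
      bases.push_back(fs);
      Q.insert_cols(Q.n_cols, r / nr);
    }
    arma::vec yres_new = y - Q * (Q.t() * y);
    double rss_new = arma::dot(yres_new, yres_new);
    yres = yres_new;
    rss = rss_new;
  }

  List fl(bases.size());
  for (size_t i = 0; i < bases.size(); ++i) {
    IntegerVector var(bases[i].size()), dir(bases[i].size());
    NumericVector knot(bases[i].size());
    for (size_t j = 0; j < bases[i].size(); ++j) {
      var[j] = bases[i][j].var + 1;  // 1-based for R
      knot[j] = bases[i][j].knot;
      dir[j] = bases[i][j].dir;
    }
    fl[i] = DataFrame::create(_["var"] = var, _["knot"] = knot, _["dir"] = dir);
  }
  return List::create(_["bases"] = fl, _["rss"] = rss,
                      _["degenerate_stop"] = stopped_degenerate);
}
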