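#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted LASSO path by cyclic coordinate descent with per-feature penalty
// factors: soft-thresholding on (weighted-centered) columns, warm starts down
// a descending lambda grid, and active-set iteration between full passes.
//
// Contract expected from the R wrapper:
//   * columns of X are weighted-centered (weighted mean 0); y likewise;
//   * w sums to n (so (1/n) sum_i w_i x_ij^2 is the working curvature d_j);
//   * vf[j] >= 0, may be Inf (feature excluded from the model entirely);
//   * lambda is strictly descending.
//
// Objective: (1/(2n)) sum_i w_i (y_i - x_i' b)^2 + lambda * sum_j vf_j |b_j|.
//
// Convergence per lambda: a full cyclic pass changes no coefficient by more
// than tol AND the max KKT violation over all coordinates is < kkt_tol.
//
// Path early stops (applied after a converged lambda is recorded):
//   * dev_stop: the fraction of weighted variance explained exceeds rsq_max,
//     or improves by less than fdev * rsq over the previous lambda;
//   * df_max: the active set has grown beyond df_max (saturated models that
//     out-of-fold MSE selection cannot choose).
// n_used reports how many grid points were solved.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return -(-z - t);
  return 0.0;
}

// [[Rcpp::export]]
List cd_lasso_path_cpp(const NumericMatrix& X, const NumericVector& y,
                       const NumericVector& w, const NumericVector& vf,
                       const NumericVector& lambda, double tol,
                       int max_iter, double kkt_tol,
                       bool dev_stop = false, double fdev = 1e-5,
                       double rsq_max = 0.999, double df_max = R_PosInf) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
  const double* xp = X.begin();

  // Precompute w*x columns and curvatures d_j = (1/n) sum w x^2.
  std::vector<double> WX((size_t)n * p);
  std::vector<double> d(p);
  for (int j = 0; j < p; ++j) {
    const double* xj = xp + (size_t)j * n;
    double* wxj = WX.data() + (size_t)j * n;
    double dj = 0.0;
    for (int i = 0; i < n; ++i) {
      wxj[i] = w[i] * xj[i];
      dj += wxj[i] * xj[i];
    }
    d[j] = dj / n;
  }
  double null_dev = 0.0;
  for (int i = 0; i < n; ++i) null_dev += w[i] * y[i] * y[i];
  null_dev /= n;

  NumericMatrix beta(p, nlam);
  IntegerVector iters(nlam);
  NumericVector kkt(nlam), rsq(nlam);
  LogicalVector converged(nlam);

  std::vector<double> b(p, 0.0), r(y.begin(), y.end());

  std::vector<bool> usable(p);
  for (int j = 0; j < p; ++j)
    usable[j] = R_finite(vf[j]) && d[j] > 0.0;

  int n_used = 0;
  double rsq_prev = 0.0;

  // One coordinate visit; returns |delta|.
  auto visit = [&](int j, double lam) -> double {
    const double* wxj = WX.data() + (size_t)j * n;
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += wxj[i] * r[i];
    g /= n;
    double z = g + d[j] * b[j];
    double bn = soft(z, lam * vf[j]) / d[j];
    double delta = bn - b[j];
    if (delta != 0.0) {
      const double* xj = xp + (size_t)j * n;
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * delta;
      b[j] = bn;
      return std::fabs(delta);
    }
    return 0.0;
  };

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambda[l];
    int it = 0;
    bool ok = false;
    double maxviol = 0.0;

    while (it < max_iter) {
      // Full cyclic pass.
      double maxdelta = 0.0;
      ++it;
      for (int j = 0; j < p; ++j) {
        if (!usable[j]) continue;
        double ad = visit(j, lam);
        if (ad > maxdelta) maxdelta = ad;
      }

      if (maxdelta < tol) {
        // Check KKT over all coordinates before declaring convergence.
        maxviol = 0.0;
        for (int j = 0; j < p; ++j) {
          if (!usable[j]) continue;
          const double* wxj = WX.data() + (size_t)j * n;
          double g = 0.0;
          for (int i = 0; i < n; ++i) g += wxj[i] * r[i];
          g /= n;
          double viol;
          if (b[j] == 0.0)
            viol = std::max(0.0, std::fabs(g) - lam * vf[j]);
          else
            viol = std::fabs(g - lam * vf[j] * ((b[j] > 0) ? 1.0 : -1.0));
          if (viol > maxviol) maxviol = viol;
        }
        if (maxviol < kkt_tol) { ok = true; break; }
        continue;  // violations remain: more full passes
      }

      // Iterate on the active (nonzero) set until stable, then re-check all.
      std::vector<int> act;
      act.reserve(p);
      for (int j = 0; j < p; ++j)
        if (usable[j] && b[j] != 0.0) act.push_back(j);
      while (it < max_iter) {
        double mx = 0.0;
        ++it;
        for (size_t a = 0; a < act.size(); ++a) {
          double ad = visit(act[a], lam);
          if (ad > mx) mx = ad;
        }
        if (mx < tol) break;
      }
    }

    double* bl = beta.begin() + (size_t)l * p;
    int nz = 0;
    for (int j = 0; j < p; ++j) { bl[j] = b[j]; if (b[j] != 0.0) ++nz; }
    iters[l] = it;
    kkt[l] = maxviol;
    converged[l] = ok;
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += w[i] * r[i] * r[i];
    rsq[l] = 1.0 - (rss / n) / null_dev;
    n_used = l + 1;
    if (ok && nz > df_max) break;
    if (dev_stop && l > 0 && ok &&
        (rsq[l] > rsq_max || (rsq[l] - rsq_prev) < fdev * rsq[l]))
      break;
    rsq_prev = rsq[l];
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["beta"] = beta, _["iters"] = iters,
                      _["kkt"] = kkt, _["converged"] = converged,
                      _["rsq"] = rsq, _["n_used"] = n_used);
}
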