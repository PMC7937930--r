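#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial conditions, matching the
// usual lfilter(b, a, x, zi) contract. a[0] must be 1.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nf = std::max(na, nb);
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  int n = x.size();
  NumericVector y(n);
  std::vector<double> z(nf - 1, 0.0);
  for (int i = 0; i < nf - 1 && i < zi.size(); ++i) z[i] = zi[i];
  for (int m = 0; m < n; ++m) {
    double xm = x[m];
    double ym = bb[0] * xm + z[0];
    for (int i = 0; i < nf - 2; ++i)
      z[i] = bb[i + 1] * xm + z[i + 1] - aa[i + 1] * ym;
    z[nf - 2] = bb[nf - 1] * xm - aa[nf - 1] * ym;
    y[m] = ym;
  }
  return y;
}

static inline bool in_sorted(const IntegerVector& v, int x) {
  return std::binary_search(v.begin(), v.end(), x);
}

// Gaussian kernel weights over source vertices for a given center column of
// the geodesic distance matrix; returns the unit-sum weights and fills
// wSy = w'Sy and wGw = w'Gw needed for the profiled Gaussian log-likelihood.
static void kernel_stats(const NumericMatrix& D, const NumericMatrix& G,
                         const NumericVector& Sy, int c, double sigma,
                         std::vector<double>& w, double& wSy, double& wGw) {
  int n = D.nrow();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double tot = 0.0;
  for (int j = 0; j < n; ++j) {
    double d = D(j, c);
    double wj = std::exp(-d * d * inv2s2);
    w[j] = wj;
    tot += wj;
  }
  wSy = 0.0; wGw = 0.0;
  double inv = 1.0 / tot;
  for (int j = 0; j < n; ++j) {
    w[j] *= inv;
    wSy += w[j] * Sy[j];
  }
  for (int j = 0; j < n; ++j) {
    if (w[j] < 1e-14) continue;      // negligible weight, skip Gram row
    const double wj = w[j];
    double acc = 0.0;
    for (int k = 0; k < n; ++k) acc += w[k] * G(k, j);
    wGw += wj * acc;
  }
}

static inline double log_post_kernel(double wSy, double wGw, double beta,
                                     double yty, double nT, double sigma) {
  double rss = yty - 2.0 * beta * wSy + beta * beta * wGw;
  double floor_ = 1e-12 * yty;
  if (rss < floor_) rss = floor_;
  // profiled-noise Gaussian likelihood + log-uniform prior on sigma
  return -0.5 * nT * std::log(rss) - std::log(sigma);
}

// Random-walk Metropolis-Hastings over (center, log sigma, beta).
// D: source x source geodesic distances; G = S S'; Sy = S y; yty = y'y.
// neighbors: per-source-vertex sorted 0-based k-ring neighborhoods.
// Returns matrix [n_iter x 4]: center (0-based), sigma, beta, log-posterior,
// plus acceptance counts as an attribute.
// [[Rcpp::export(name = ".cf_mcmc_cpp")]]
NumericMatrix cf_mcmc_cpp(NumericMatrix D, NumericMatrix G, NumericVector Sy,
                          double yty, double nT, List neighbors,
                          int n_iter, int c0, double sigma0, double beta0,
                          double sigma_min, double sigma_max, double beta_max,
                          double sigma_step, double beta_step, double p_global) {
  int n = D.nrow();
  std::vector<double> w(n), wprop(n);
  int cur_c = c0;
  double cur_sigma = sigma0, cur_beta = beta0;
  double cur_wSy, cur_wGw, dummySy, dummyGw;
  kernel_stats(D, G, Sy, cur_c, cur_sigma, w, cur_wSy, cur_wGw);
  double cur_lp = log_post_kernel(cur_wSy, cur_wGw, cur_beta, yty, nT, cur_sigma);

  NumericMatrix out(n_iter, 4);
  int acc_c = 0, acc_s = 0, acc_b = 0;
  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // --- center update (mixture proposal: k-ring walk + global jump) ---
    {
      IntegerVector nb_cur = neighbors[cur_c];
      int prop_c;
      if (R::unif_rand() < p_global) {
        prop_c = (int)(R::unif_rand() * n);
        if (prop_c >= n) prop_c = n - 1;
      } else {
        int k = (int)(R::unif_rand() * nb_cur.size());
        if (k >= nb_cur.size()) k = nb_cur.size() - 1;
        prop_c = nb_cur[k];
      }
      if (prop_c != cur_c) {
        IntegerVector nb_prop = neighbors[prop_c];
        double q_fwd = p_global / n +
          (in_sorted(nb_cur, prop_c) ? (1.0 - p_global) / nb_cur.size() : 0.0);
        double q_bwd = p_global / n +
          (in_sorted(nb_prop, cur_c) ? (1.0 - p_global) / nb_prop.size() : 0.0);
        kernel_stats(D, G, Sy, prop_c, cur_sigma, wprop, dummySy, dummyGw);
        double lp = log_post_kernel(dummySy, dummyGw, cur_beta, yty, nT, cur_sigma);
        if (std::log(R::unif_rand()) < lp - cur_lp + std::log(q_bwd) - std::log(q_fwd)) {
          cur_c = prop_c; cur_lp = lp; cur_wSy = dummySy; cur_wGw = dummyGw;
          ++acc_c;
        }
      }
    }
    // --- sigma update (Gaussian step on log sigma) ---
    {
      double prop_sigma = std::exp(std::log(cur_sigma) + sigma_step * R::norm_rand());
      if (prop_sigma >= sigma_min && prop_sigma <= sigma_max) {
        kernel_stats(D, G, Sy, cur_c, prop_sigma, wprop, dummySy, dummyGw);
        double lp = log_post_kernel(dummySy, dummyGw, cur_beta, yty, nT, prop_sigma);
        // log-scale random walk is symmetric in log sigma; the Jacobian of
        // the exp transform cancels against the proposal density
        if (std::log(R::unif_rand()) < lp - cur_lp) {
          cur_sigma = prop_sigma; cur_lp = lp;
          cur_wSy = dummySy; cur_wGw = dummyGw;
          ++acc_s;
        }
      }
    }
    // --- beta update (Gaussian step, kernel stats unchanged) ---
    {
      double prop_beta = cur_beta + beta_step * R::norm_rand();
      if (prop_beta >= 0.0 && prop_beta <= beta_max) {
        double lp = log_post_kernel(cur_wSy, cur_wGw, prop_beta, yty, nT, cur_sigma);
        if (std::log(R::unif_rand()) < lp - cur_lp) {
          cur_beta = prop_beta; cur_lp = lp;
          ++acc_b;
        }
      }
    }
    out(it, 0) = cur_c;
    out(it, 1) = cur_sigma;
    out(it, 2) = cur_beta;
    out(it, 3) = cur_lp;
  }
  out.attr("acceptance") = NumericVector::create(
    _["center"] = (double)acc_c / n_iter,
    _["sigma"]  = (double)acc_s / n_iter,
    _["beta"]   = (double)acc_b / n_iter);
  return out;
}
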