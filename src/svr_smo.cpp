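#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Pairwise squared Euclidean distances between rows of X and rows of Y.
// [[Rcpp::export(rng = false)]]
NumericMatrix sqdist_cpp(NumericMatrix X, NumericMatrix Y) {
  const int nx = X.nrow(), ny = Y.nrow(), d = X.ncol();
  if (Y.ncol() != d) stop("sqdist_cpp: column mismatch");
  NumericMatrix D(nx, ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = X(i, k) - Y(j, k);
        s += diff * diff;
      }
      D(i, j) = s;
    }
  }
  return D;
}

// Elementwise RBF kernel from a squared-distance matrix: exp(-gamma * D).
// [[Rcpp::export(rng = false)]]
NumericMatrix rbf_from_sqdist_cpp(NumericMatrix D, double gamma) {
  const int n = D.nrow(), m = D.ncol();
  NumericMatrix K(n, m);
  const double* d = D.begin();
  double* k = K.begin();
  const R_xlen_t len = (R_xlen_t)n * m;
  for (R_xlen_t i = 0; i < len; ++i) k[i] = std::exp(-gamma * d[i]);
  return K;
}

// Sequential minimal optimization for the epsilon-SVR dual.
//
// 2n-variable formulation: t < n are the lambda (z = +1) variables with
// linear term eps - y_t, t >= n the lambda* (z = -1) variables with
// eps + y_{t-n}; all bounded in [0, cost] under sum(z * alpha) = 0.
// Maximal-violating-pair selection; gradient maintained incrementally with
// two kernel rows per update. Returns beta = lambda - lambda*, the bias, and
// convergence information.
// [[Rcpp::export(rng = false)]]
List svr_smo_cpp(NumericMatrix K, NumericVector y, double cost, double eps,
                 double tol, int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("svr_smo_cpp: size mismatch");
  if (cost <= 0.0) stop("svr_smo_cpp: cost must be positive");
  if (eps < 0.0) stop("svr_smo_cpp: eps must be non-negative");

  const int m = 2 * n;
  std::vector<double> alpha(m, 0.0), G(m), z(m);
  for (int t = 0; t < n; ++t) {
    G[t] = eps - y[t];
    G[t + n] = eps + y[t];
    z[t] = 1.0;
    z[t + n] = -1.0;
  }

  int iter = 0;
  bool converged = false;
  for (; iter < max_iter; ++iter) {
    // second-order working set selection: i maximises -z G over I_up;
    // j minimises the one-step objective decrease -b^2/a over the violating
    // members of I_low (LibSVM's WSS2)
    int i = -1;
    double gmax = -HUGE_VAL, gmin = HUGE_VAL;
    for (int t = 0; t < m; ++t) {
      const double v = -z[t] * G[t];
      const bool up = (z[t] > 0.0) ? (alpha[t] < cost) : (alpha[t] > 0.0);
      const bool low = (z[t] > 0.0) ? (alpha[t] > 0.0) : (alpha[t] < cost);
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) gmin = v;
    }
    if (i < 0 || gmax - gmin < tol) { converged = true; break; }

    const int si = i % n;
    const double Kii = K(si, si);
    int j = -1;
    double obj_min = HUGE_VAL, step_ij = 0.0;
    for (int t = 0; t < m; ++t) {
      const bool low = (z[t] > 0.0) ? (alpha[t] > 0.0) : (alpha[t] < cost);
      if (!low) continue;
      const double b = gmax + z[t] * G[t];      // gmax - (-z_t G_t)
      if (b <= 0.0) continue;
      double a = Kii + K(t % n, t % n) - 2.0 * K(si, t % n);
      if (a <= 0.0) a = 1e-12;
      const double dec = -(b * b) / a;
      if (dec < obj_min) { obj_min = dec; j = t; step_ij = b / a; }
    }
    if (j < 0) { converged = true; break; }

    const int sj = j % n;
    double step = step_ij;                      // step in beta space, > 0

    // box clipping: alpha_i moves by +z_i*step, alpha_j by -z_j*step
    double lim = (z[i] > 0.0) ? (cost - alpha[i]) : alpha[i];
    if (step > lim) step = lim;
    lim = (z[j] > 0.0) ? alpha[j] : (cost - alpha[j]);
    if (step > lim) step = lim;
    if (step <= 0.0) { converged = true; break; }

    alpha[i] += z[i] * step;
    alpha[j] -= z[j] * step;

    // gradient update: G_t += z_t * step * (K(t, si) - K(t, sj))
    for (int t = 0; t < n; ++t) {
      const double dk = step * (K(t, si) - K(t, sj));
      G[t] += dk;
      G[t + n] -= dk;
    }
  }

  NumericVector beta(n);
  for (int t = 0; t < n; ++t) beta[t] = alpha[t] - alpha[t + n];

  // bias from free variables (strictly inside the box), else the midpoint of
  // the final violating-pair bounds
  double bias_sum = 0.0;
  int n_free = 0;
  double gmax = -HUGE_VAL, gmin = HUGE_VAL;
  for (int t = 0; t < m; ++t) {
    const double v = -z[t] * G[t];
    if (alpha[t] > 0.0 && alpha[t] < cost) { bias_sum += v; ++n_free; }
    const bool up = (z[t] > 0.0) ? (alpha[t] < cost) : (alpha[t] > 0.0);
    const bool low = (z[t] > 0.0) ? (alpha[t] > 0.0) : (alpha[t] < cost);
    if (up && v > gmax) gmax = v;
    if (low && v < gmin) gmin = v;
  }
  double bias;
  if (n_free > 0) {
    bias = bias_sum / n_free;
  } else if (std::isfinite(gmax) && std::isfinite(gmin)) {
    bias = 0.5 * (gmax + gmin);
  } else {
    bias = 0.0;
  }

  return List::create(_["beta"] = beta, _["bias"] = bias,
                      _["iterations"] = iter, _["converged"] = converged);
}
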