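#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Strict local maxima; plateaus contribute their midpoint.
static std::vector<int> local_maxima(const std::vector<double>& p) {
  const int T = (int)p.size();
  std::vector<int> out;
  int i = 1;
  while (i < T - 1) {
    if (p[i] > p[i - 1]) {
      if (p[i] > p[i + 1]) {
        out.push_back(i);
        ++i;
        continue;
      }
      if (p[i] == p[i + 1]) {
        int j = i;
        while (j + 1 < T && p[j + 1] == p[i]) ++j;
        if (j < T - 1 && p[j + 1] < p[i]) out.push_back((i + j) / 2);
        i = j + 1;
        continue;
      }
    }
    ++i;
  }
  return out;
}

// Natural cubic spline through (x, y), x strictly increasing; evaluated at
// integer abscissae 0..T-1.  End intervals extrapolate with the end cubic.
static void natural_spline_eval(const std::vector<double>& x,
                                const std::vector<double>& y,
                                int T, double* out) {
  const int n = (int)x.size();
  if (n == 2) {  // linear fallback
    const double slope = (y[1] - y[0]) / (x[1] - x[0]);
    for (int t = 0; t < T; ++t) out[t] = y[0] + slope * (t - x[0]);
    return;
  }
  std::vector<double> h(n - 1), alpha(n), l(n), mu(n), z(n), c(n), b(n - 1), d(n - 1);
  for (int i = 0; i < n - 1; ++i) h[i] = x[i + 1] - x[i];
  for (int i = 1; i < n - 1; ++i)
    alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < n - 1; ++i) {
    l[i] = 2.0 * (x[i + 1] - x[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  c[n - 1] = 0.0;
  for (int i = n - 2; i >= 0; --i) {
    c[i] = z[i] - mu[i] * c[i + 1];
    b[i] = (y[i + 1] - y[i]) / h[i] - h[i] * (c[i + 1] + 2.0 * c[i]) / 3.0;
    d[i] = (c[i + 1] - c[i]) / (3.0 * h[i]);
  }
  int seg = 0;
  for (int t = 0; t < T; ++t) {
    while (seg < n - 2 && x[seg + 1] < (double)t) ++seg;
    const double dx = t - x[seg];
    out[t] = y[seg] + dx * (b[seg] + dx * (c[seg] + dx * d[seg]));
  }
}

// Mean of the K directional maxima envelopes of a T x n multichannel signal.
// dirs is n x K (unit direction vectors in columns).  Directions whose
// projection has fewer than 3 local maxima are skipped; n_valid reports how
// many directions contributed.  Extrema are mirror-extended (up to two at
// each end) before spline interpolation.
// [[Rcpp::export]]
List envelope_mean_cpp(NumericMatrix X, NumericMatrix dirs) {
  const int T = X.nrow(), n = X.ncol(), K = dirs.ncol();
  if (dirs.nrow() != n) stop("direction dimension must equal channel count");
  NumericMatrix acc(T, n);
  int n_valid = 0;
  std::vector<double> p(T);
  std::vector<double> env(T);

  for (int k = 0; k < K; ++k) {
    for (int t = 0; t < T; ++t) {
      double s = 0.0;
      for (int ch = 0; ch < n; ++ch) s += X(t, ch) * dirs(ch, k);
      p[t] = s;
    }
    std::vector<int> ext = local_maxima(p);
    const int E = (int)ext.size();
    if (E < 3) continue;
    ++n_valid;

    // mirror-extended knot times (values are channel-dependent, indices not)
    std::vector<double> xt;
    std::vector<int> src;  // row index of X supplying the value at each knot
    if (-(double)ext[1] < (double)ext[0]) { xt.push_back(-(double)ext[1]); src.push_back(ext[1]); }
    if (-(double)ext[0] < (double)ext[0]) { xt.push_back(-(double)ext[0]); src.push_back(ext[0]); }
    for (int e = 0; e < E; ++e) { xt.push_back((double)ext[e]); src.push_back(ext[e]); }
    const double R = 2.0 * (T - 1);
    if (R - ext[E - 1] > (double)ext[E - 1]) { xt.push_back(R - ext[E - 1]); src.push_back(ext[E - 1]); }
    if (R - ext[E - 2] > xt.back()) { xt.push_back(R - ext[E - 2]); src.push_back(ext[E - 2]); }

    const int nk = (int)xt.size();
    std::vector<double> yv(nk);
    for (int ch = 0; ch < n; ++ch) {
      for (int q = 0; q < nk; ++q) yv[q] = X(src[q], ch);
      natural_spline_eval(xt, yv, T, env.data());
      for (int t = 0; t < T; ++t) acc(t, ch) += env[t];
    }
  }
  if (n_valid > 0)
    for (int ch = 0; ch < n; ++ch)
      for (int t = 0; t < T; ++t) acc(t, ch) /= (double)n_valid;
  return List::create(_["mean"] = acc, _["n_valid"] = n_valid);
}
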