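#include <Rcpp.h>
using namespace Rcpp;

// Interior local extrema with plateau merging: a run of equal values that is
// strictly above (below) both neighbouring runs contributes the centre index
// of the run once. Runs touching either boundary are never extrema.
static void extrema_scan(const NumericVector& x,
                         std::vector<int>& maxima,
                         std::vector<int>& minima) {
  const int n = x.size();
  maxima.clear(); minima.clear();
  if (n < 3) return;
  // compress into runs of equal value
  std::vector<int> rstart, rend;
  std::vector<double> rval;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[j + 1] == x[i]) ++j;
    rstart.push_back(i); rend.push_back(j); rval.push_back(x[i]);
    i = j + 1;
  }
  const int R = (int)rstart.size();
  for (int r = 1; r + 1 < R; ++r) {
    const int centre = (rstart[r] + rend[r]) / 2 + 1;  // 1-based
    if (rval[r] > rval[r - 1] && rval[r] > rval[r + 1]) maxima.push_back(centre);
    else if (rval[r] < rval[r - 1] && rval[r] < rval[r + 1]) minima.push_back(centre);
  }
}

// [[Rcpp::export]]
List cpp_find_extrema(NumericVector x) {
  std::vector<int> maxima, minima;
  extrema_scan(x, maxima, minima);
  return List::create(_["maxima"] = wrap(maxima), _["minima"] = wrap(minima));
}

// Natural cubic spline through (xs, ys) (xs strictly increasing), evaluated
// at 1..n. Tridiagonal solve for second derivatives, natural boundary.
static void natural_spline_eval(const std::vector<double>& xs,
                                const std::vector<double>& ys,
                                NumericVector& out) {
  const int m = (int)xs.size();
  const int n = out.size();
  if (m == 2) {
    const double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int t = 0; t < n; ++t) out[t] = ys[0] + slope * ((t + 1) - xs[0]);
    return;
  }
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), c(m);
  for (int k = 0; k < m - 1; ++k) h[k] = xs[k + 1] - xs[k];
  for (int k = 1; k < m - 1; ++k)
    alpha[k] = 3.0 * ((ys[k + 1] - ys[k]) / h[k] - (ys[k] - ys[k - 1]) / h[k - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int k = 1; k < m - 1; ++k) {
    l[k] = 2.0 * (xs[k + 1] - xs[k - 1]) - h[k - 1] * mu[k - 1];
    mu[k] = h[k] / l[k];
    z[k] = (alpha[k] - h[k - 1] * z[k - 1]) / l[k];
  }
  l[m - 1] = 1.0; z[m - 1] = 0.0; c[m - 1] = 0.0;
  for (int k = m - 2; k >= 0; --k) c[k] = z[k] - mu[k] * c[k + 1];
  // piecewise evaluation; query points 1..n are sorted, walk segments once
  int seg = 0;
  for (int t = 0; t < n; ++t) {
    const double xq = t + 1;
    while (seg < m - 2 && xq > xs[seg + 1]) ++seg;
    const double dx = xq - xs[seg];
    const double b = (ys[seg + 1] - ys[seg]) / h[seg] -
                     h[seg] * (c[seg + 1] + 2.0 * c[seg]) / 3.0;
    const double d = (c[seg + 1] - c[seg]) / (3.0 * h[seg]);
    out[t] = ys[seg] + b * dx + c[seg] * dx * dx + d * dx * dx * dx;
  }
}

// Envelope knots: extrema mirrored about both ends (two nearest each end).
static void build_knots(const NumericVector& x, const std::vector<int>& idx,
                        int n, std::vector<double>& xs, std::vector<double>& ys) {
  const int m = (int)idx.size();
  xs.clear(); ys.clear();
  // left mirror: reflect the two extrema nearest the first sample about it
  xs.push_back(2.0 - idx[1]); ys.push_back(x[idx[1] - 1]);
  xs.push_back(2.0 - idx[0]); ys.push_back(x[idx[0] - 1]);
  for (int k = 0; k < m; ++k) { xs.push_back(idx[k]); ys.push_back(x[idx[k] - 1]); }
  xs.push_back(2.0 * n - idx[m - 1]); ys.push_back(x[idx[m - 1] - 1]);
  xs.push_back(2.0 * n - idx[m - 2]); ys.push_back(x[idx[m - 2] - 1]);
}

static bool envelope_mean_inner(const NumericVector& x, NumericVector& mean_env) {
  std::vector<int> maxima, minima;
  extrema_scan(x, maxima, minima);
  if (maxima.size() < 2 || minima.size() < 2) return false;
  const int n = x.size();
  std::vector<double> xs, ys;
  NumericVector upper(n), lower(n);
  build_knots(x, maxima, n, xs, ys);
  natural_spline_eval(xs, ys, upper);
  build_knots(x, minima, n, xs, ys);
  natural_spline_eval(xs, ys, lower);
  for (int t = 0; t < n; ++t) mean_env[t] = 0.5 * (upper[t] + lower[t]);
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_envelope_mean(NumericVector x) {
  NumericVector m(x.size());
  if (!envelope_mean_inner(x, m)) stop("decomposition-exhausted");
  return m;
}

static int count_zero_crossings(const NumericVector& x) {
  int zc = 0, last = 0;
  for (int t = 0; t < x.size(); ++t) {
    const int s = (x[t] > 0) - (x[t] < 0);
    if (s != 0) {
      if (last != 0 && s != last) ++zc;
      last = s;
    }
  }
  return zc;
}

// One sifting pass to extract a single IMF from x.
// Stops on the Cauchy criterion sum((h_prev-h)^2)/sum(h_prev^2) < sd_thresh,
// or when |#extrema - #zero-crossings| <= 1 for s_number consecutive
// iterations, capped at max_iter.
static List sift_inner(const NumericVector& x, double sd_thresh, int s_number,
                       int max_iter) {
  NumericVector h = clone(x);
  NumericVector m(h.size());
  bool converged = false;
  int it = 0, stable = 0;
  while (it < max_iter) {
    if (!envelope_mean_inner(h, m)) { converged = true; break; }
    double num = 0.0, den = 0.0;
    for (int t = 0; t < h.size(); ++t) {
      num += m[t] * m[t];
      den += h[t] * h[t];
    }
    for (int t = 0; t < h.size(); ++t) h[t] -= m[t];
    ++it;
    std::vector<int> maxima, minima;
    extrema_scan(h, maxima, minima);
    const int next = (int)(maxima.size() + minima.size());
    const int zc = count_zero_crossings(h);
    if (std::abs(next - zc) <= 1) ++stable; else stable = 0;
    if (den > 0.0 && num / den < sd_thresh) { converged = true; break; }
    if (stable >= s_number) { converged = true; break; }
  }
  return List::create(_["imf"] = h, _["iterations"] = it,
                      _["converged"] = converged);
}

// [[Rcpp::export]]
List cpp_sift(NumericVector x, double sd_thresh, int s_number, int max_iter) {
  return sift_inner(x, sd_thresh, s_number, max_iter);
}

// [[Rcpp::export]]
List cpp_decompose(NumericVector x, int max_imfs, double sd_thresh,
                   int s_number, int max_iter) {
  NumericVector residual = clone(x);
  List imfs(max_imfs);
  int k = 0, unconverged = 0;
  while (k < max_imfs) {
    std::vector<int> maxima, minima;
    extrema_scan(residual, maxima, minima);
    if (maxima.size() < 2 || minima.size() < 2) break;
    List s = sift_inner(residual, sd_thresh, s_number, max_iter);
    NumericVector imf = s["imf"];
    if (!as<bool>(s["converged"])) ++unconverged;
    for (int t = 0; t < residual.size(); ++t) residual[t] -= imf[t];
    imfs[k] = imf;
    ++k;
  }
  List out(k);
  for (int j = 0; j < k; ++j) out[j] = imfs[j];
  return List::create(_["imfs"] = out, _["residual"] = residual,
                      _["n_unconverged"] = unconverged);
}

// Normalized cross-correlation by direct summation, divisor N fixed:
// r(k) = sum_t (x[t+k]-xbar)(y[t]-ybar) / (N * sx * sy), overlap-only sums.
// [[Rcpp::export]]
NumericVector cpp_crosscorr(NumericVector x, NumericVector y, int max_lag) {
  const int n = x.size();
  double xb = 0.0, yb = 0.0;
  for (int t = 0; t < n; ++t) { xb += x[t]; yb += y[t]; }
  xb /= n; yb /= n;
  double vx = 0.0, vy = 0.0;
  for (int t = 0; t < n; ++t) {
    vx += (x[t] - xb) * (x[t] - xb);
    vy += (y[t] - yb) * (y[t] - yb);
  }
  const double sx = std::sqrt(vx / n), sy = std::sqrt(vy / n);
  NumericVector r(2 * max_lag + 1);
  if (sx == 0.0 || sy == 0.0) return r;  // caller flags zero-variance input
  for (int k = -max_lag; k <= max_lag; ++k) {
    const int t0 = std::max(0, -k), t1 = std::min(n, n - k);
    double s = 0.0;
    for (int t = t0; t < t1; ++t) s += (x[t + k] - xb) * (y[t] - yb);
    r[k + max_lag] = s / (n * sx * sy);
  }
  return r;
}

// Kellet three-pole pink-noise filter applied to white noise input.
// [[Rcpp::export]]
NumericVector cpp_kellet(NumericVector w) {
  const int n = w.size();
  NumericVector p(n);
  double b0 = 0.0, b1 = 0.0, b2 = 0.0;
  for (int t = 0; t < n; ++t) {
    b0 = 0.99765 * b0 + 0.0990460 * w[t];
    b1 = 0.96300 * b1 + 0.2965164 * w[t];
    b2 = 0.57000 * b2 + 1.0526913 * w[t];
    p[t] = b0 + b1 + b2 + 0.1848 * w[t];
  }
  return p;
}
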