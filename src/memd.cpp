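// Multivariate empirical mode decomposition: directional-projection sifting
// with cubic-spline envelopes. Hot loop of the package, hence C++.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Natural cubic spline through (xs, ys), xs strictly increasing, evaluated at
// t = 0, 1, ..., T-1. Knots are mirror-extended by the caller so [0, T-1] is
// always inside [xs.front(), xs.back()]; values outside are extrapolated
// linearly as a guard.
static void spline_grid(const std::vector<double> &xs,
                        const std::vector<double> &ys,
                        int T, std::vector<double> &out) {
  const int n = (int)xs.size();
  out.assign(T, 0.0);
  if (n == 1) {
    for (int t = 0; t < T; ++t) out[t] = ys[0];
    return;
  }
  if (n == 2) {
    double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int t = 0; t < T; ++t) out[t] = ys[0] + slope * (t - xs[0]);
    return;
  }
  // second derivatives M: natural boundary (M0 = Mn-1 = 0), Thomas algorithm
  std::vector<double> h(n - 1), alpha(n), l(n), mu(n), z(n), M(n);
  for (int i = 0; i < n - 1; ++i) h[i] = xs[i + 1] - xs[i];
  alpha[0] = 0.0;
  for (int i = 1; i < n - 1; ++i)
    alpha[i] = 3.0 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < n - 1; ++i) {
    l[i] = 2.0 * (xs[i + 1] - xs[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[n - 1] = 0.0;
  for (int i = n - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  // evaluate; knot intervals scanned left to right alongside t
  int seg = 0;
  for (int t = 0; t < T; ++t) {
    double x = (double)t;
    if (x <= xs[0]) {
      double d = (ys[1] - ys[0]) / h[0] - h[0] * (2.0 * M[0] + M[1]) / 6.0;
      out[t] = ys[0] + d * (x - xs[0]);
      continue;
    }
    if (x >= xs[n - 1]) {
      double d = (ys[n - 1] - ys[n - 2]) / h[n - 2] +
                 h[n - 2] * (M[n - 2] + 2.0 * M[n - 1]) / 6.0;
      out[t] = ys[n - 1] + d * (x - xs[n - 1]);
      continue;
    }
    while (seg < n - 2 && xs[seg + 1] < x) ++seg;
    double a = xs[seg], b = xs[seg + 1], hh = b - a;
    double A = (b - x) / hh, B = (x - a) / hh;
    out[t] = A * ys[seg] + B * ys[seg + 1] +
             ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) *
                 hh * hh / 6.0;
  }
}

// strict local extrema of p; plateaus contribute no extremum
static void find_extrema(const std::vector<double> &p,
                         std::vector<int> &mx, std::vector<int> &mn) {
  mx.clear(); mn.clear();
  const int T = (int)p.size();
  for (int t = 1; t < T - 1; ++t) {
    if (p[t] > p[t - 1] && p[t] > p[t + 1]) mx.push_back(t);
    else if (p[t] < p[t - 1] && p[t] < p[t + 1]) mn.push_back(t);
  }
}

// mirror-extend up to n_ext extrema about both signal ends (t = 0, T-1)
static void mirror_extend(const std::vector<int> &idx, int T, int n_ext,
                          std::vector<double> &xs, std::vector<int> &src) {
  xs.clear(); src.clear();
  const int n = (int)idx.size();
  // pushing the 2nd extremum first keeps the mirrored knots ascending
  for (int i = std::min(n_ext, n) - 1; i >= 0; --i) {
    if (idx[i] > 0) { xs.push_back(-(double)idx[i]); src.push_back(idx[i]); }
  }
  for (int i = 0; i < n; ++i) { xs.push_back((double)idx[i]); src.push_back(idx[i]); }
  for (int i = n - 1; i >= std::max(0, n - n_ext); --i) {
    if (idx[i] < T - 1) {
      xs.push_back(2.0 * (T - 1) - idx[i]);
      src.push_back(idx[i]);
    }
  }
}

// envelope (T x d) through the signal rows at knot times given by src indices
static void envelope(const NumericMatrix &h, const std::vector<double> &xs,
                     const std::vector<int> &src, std::vector<double> &buf,
                     std::vector<std::vector<double> > &env) {
  const int T = h.nrow(), d = h.ncol();
  std::vector<double> ys(xs.size());
  for (int c = 0; c < d; ++c) {
    for (size_t i = 0; i < src.size(); ++i) ys[i] = h(src[i], c);
    spline_grid(xs, ys, T, buf);
    for (int t = 0; t < T; ++t) env[c][t] = buf[t];
  }
}

// mean envelope over directions; returns number of usable directions
static int mean_envelope(const NumericMatrix &h, const NumericMatrix &dirs,
                         NumericMatrix &m) {
  const int T = h.nrow(), d = h.ncol(), K = dirs.nrow();
  std::fill(m.begin(), m.end(), 0.0);
  std::vector<double> p(T), buf;
  std::vector<int> mx, mn, src;
  std::vector<double> xs;
  std::vector<std::vector<double> > eup(d, std::vector<double>(T)),
      edn(d, std::vector<double>(T));
  int used = 0;
  for (int k = 0; k < K; ++k) {
    for (int t = 0; t < T; ++t) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) s += h(t, c) * dirs(k, c);
      p[t] = s;
    }
    find_extrema(p, mx, mn);
    if ((int)mx.size() < 2 || (int)mn.size() < 2) continue;
    mirror_extend(mx, T, 2, xs, src);
    envelope(h, xs, src, buf, eup);
    mirror_extend(mn, T, 2, xs, src);
    envelope(h, xs, src, buf, edn);
    for (int c = 0; c < d; ++c)
      for (int t = 0; t < T; ++t)
        m(t, c) += 0.5 * (eup[c][t] + edn[c][t]);
    ++used;
  }
  if (used > 0) {
    const double inv = 1.0 / used;
    for (R_xlen_t i = 0; i < m.size(); ++i) m[i] *= inv;
  }
  return used;
}

static double frob(const NumericMatrix &x) {
  double s = 0.0;
  for (R_xlen_t i = 0; i < x.size(); ++i) s += x[i] * x[i];
  return std::sqrt(s);
}

// largest projection extrema count over all directions (extraction stop rule)
static int max_proj_extrema(const NumericMatrix &h, const NumericMatrix &dirs) {
  const int T = h.nrow(), d = h.ncol(), K = dirs.nrow();
  std::vector<double> p(T);
  std::vector<int> mx, mn;
  int best = 0;
  for (int k = 0; k < K; ++k) {
    for (int t = 0; t < T; ++t) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) s += h(t, c) * dirs(k, c);
      p[t] = s;
    }
    find_extrema(p, mx, mn);
    int n = (int)(mx.size() + mn.size());
    if (n > best) best = n;
  }
  return best;
}

// [[Rcpp::export(name = ".memd_sift_cpp")]]
List memd_sift_cpp(NumericMatrix x, NumericMatrix dirs, int max_imf,
                   int max_sift, double tol) {
  const int T = x.nrow(), d = x.ncol();
  NumericMatrix resid = clone(x);
  NumericMatrix h(T, d), m(T, d);
  List imfs;
  IntegerVector sifts;
  const double energy_floor = 1e-10 * frob(x);
  while ((int)imfs.size() < max_imf) {
    if (frob(resid) <= energy_floor) break;  // numerically exhausted
    if (max_proj_extrema(resid, dirs) < 3) break;
    for (R_xlen_t i = 0; i < h.size(); ++i) h[i] = resid[i];
    int consec = 0, s;
    bool started = false;
    for (s = 0; s < max_sift; ++s) {
      int used = mean_envelope(h, dirs, m);
      if (used == 0) break;
      started = true;
      double ratio = frob(m) / std::max(frob(h), 1e-300);
      for (R_xlen_t i = 0; i < h.size(); ++i) h[i] -= m[i];
      if (ratio < tol) ++consec; else consec = 0;
      if (consec >= 2) { ++s; break; }
    }
    if (!started) break;
    NumericMatrix imf(T, d);
    for (R_xlen_t i = 0; i < h.size(); ++i) {
      imf[i] = h[i];
      resid[i] -= h[i];
    }
    imfs.push_back(imf);
    sifts.push_back(s);
  }
  return List::create(_["imfs"] = imfs, _["residual"] = resid,
                      _["sifts"] = sifts);
}
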