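#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Strict local extrema: x[i] > both neighbours (maxima) / < both (minima).
// Exact-tie plateaus are ignored; microvolt float data makes them measure-zero.
static void local_extrema(const double* x, int n,
                          std::vector<int>& maxima, std::vector<int>& minima) {
  for (int i = 1; i + 1 < n; ++i) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) maxima.push_back(i);
    else if (x[i] < x[i - 1] && x[i] < x[i + 1]) minima.push_back(i);
  }
}

// Topographic prominence of a local maximum: walk out each side until a
// strictly higher sample (or the boundary); prominence is the height above
// the higher of the two interval minima.
static double prominence_at(const double* x, int n, int i) {
  double h = x[i];
  double ml = h, mr = h;
  for (int j = i - 1; j >= 0; --j) {
    if (x[j] > h) break;
    if (x[j] < ml) ml = x[j];
  }
  for (int j = i + 1; j < n; ++j) {
    if (x[j] > h) break;
    if (x[j] < mr) mr = x[j];
  }
  return h - std::max(ml, mr);
}

// Peak selection + pairing used by detect_pairs():
//  1. candidate peaks: strict local maxima with prominence >= prom;
//  2. minimum spacing enforced greedily in order of decreasing amplitude
//     (ties broken toward the earlier sample);
//  3. each accepted peak pairs with the lowest strict local minimum before
//     the next accepted peak (or the end of the signal); peaks without a
//     following minimum are dropped.
// Returns a 4-column matrix: peak_index (1-based), peak_amp, trough_index,
// trough_amp, ordered by peak_index.
// [[Rcpp::export]]
NumericMatrix ppaf_pairs_cpp(NumericVector x, double prom, int min_sep) {
  int n = x.size();
  const double* p = REAL(x);
  std::vector<int> maxima, minima;
  local_extrema(p, n, maxima, minima);

  std::vector<int> cand;
  for (int i : maxima)
    if (prominence_at(p, n, i) >= prom) cand.push_back(i);

  std::vector<int> order(cand.size());
  for (size_t k = 0; k < cand.size(); ++k) order[k] = (int)k;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (p[cand[a]] != p[cand[b]]) return p[cand[a]] > p[cand[b]];
    return cand[a] < cand[b];
  });
  std::vector<int> accepted;
  for (int k : order) {
    int i = cand[k];
    bool ok = true;
    for (int j : accepted)
      if (std::abs(i - j) < min_sep) { ok = false; break; }
    if (ok) accepted.push_back(i);
  }
  std::sort(accepted.begin(), accepted.end());

  std::vector<double> rows;
  for (size_t k = 0; k < accepted.size(); ++k) {
    int lo = accepted[k];
    int hi = (k + 1 < accepted.size()) ? accepted[k + 1] : n;
    int best = -1;
    double bestv = R_PosInf;
    // minima are sorted; linear scan is fine at these sizes
    for (int m : minima) {
      if (m <= lo) continue;
      if (m >= hi) break;
      if (p[m] < bestv) { bestv = p[m]; best = m; }
    }
    if (best < 0) continue;
    rows.push_back(lo + 1);
    rows.push_back(p[lo]);
    rows.push_back(best + 1);
    rows.push_back(bestv);
  }
  int np = rows.size() / 4;
  NumericMatrix out(np, 4);
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = rows[4 * i + j];
  colnames(out) = CharacterVector::create("peak_index", "peak_amp",
                                          "trough_index", "trough_amp");
  return out;
}

static double median_of(std::vector<double>& v) {
  size_t n = v.size();
  if (n == 0) return NA_REAL;
  size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double m = v[mid];
  if (n % 2 == 0) {
    std::nth_element(v.begin(), v.begin() + mid - 1, v.begin() + mid);
    m = 0.5 * (m + v[mid - 1]);
  }
  return m;
}

// Sliding-window PPAF on one channel. prom = NA_real_ requests the adaptive
// default, adapt_mult * raw median absolute deviation of the window.
// Returns n_windows x 3: ppaf, n_pairs, stability_percent.
// [[Rcpp::export]]
NumericMatrix sliding_ppaf_cpp(NumericVector x, int win, int step,
                               double prom, int min_sep, double adapt_mult) {
  int n = x.size();
  int nw = (n - win) / step + 1;
  NumericMatrix out(nw, 3);
  std::vector<double> buf(win), dev(win);
  for (int w = 0; w < nw; ++w) {
    int off = w * step;
    NumericVector seg(x.begin() + off, x.begin() + off + win);
    double pr = prom;
    if (!R_finite(pr)) {
      std::copy(seg.begin(), seg.end(), buf.begin());
      double med = median_of(buf);
      for (int i = 0; i < win; ++i) dev[i] = std::fabs(seg[i] - med);
      pr = adapt_mult * median_of(dev);
    }
    NumericMatrix pairs = ppaf_pairs_cpp(seg, pr, min_sep);
    int np = pairs.nrow();
    double sum = 0, sum2 = 0;
    for (int i = 0; i < np; ++i) {
      double a = pairs(i, 1) - pairs(i, 3);
      sum += a;
      sum2 += a * a;
    }
    double ppaf = np > 0 ? sum / np : 0.0;
    double stab = 0.0;
    if (np == 1) stab = 100.0;
    else if (np > 1) {
      double var = (sum2 - sum * sum / np) / (np - 1);
      double sd = var > 0 ? std::sqrt(var) : 0.0;
      double cv = ppaf != 0 ? sd / ppaf : 0.0;
      stab = 100.0 * (1.0 - cv);
      if (stab < 0) stab = 0;
      if (stab > 100) stab = 100;
    }
    out(w, 0) = ppaf;
    out(w, 1) = np;
    out(w, 2) = stab;
  }
  colnames(out) = CharacterVector::create("ppaf", "n_pairs", "stability");
  return out;
}
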