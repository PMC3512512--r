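// Binary circular binary segmentation core.
//
// Works on a 0/1 vector (HNCN calls restricted to informative markers).
// Every circular arc corresponds to an unordered breakpoint pair {i, j}
// (0 <= i < j <= n) and the two-sample proportion statistic is symmetric
// between an arc and its complement, so scanning all non-wrapped arcs
// [i, i+l) with l = min_width .. n-min_width enumerates every candidate
// split exactly once. Significance is assessed by label permutations with
// early rejection as soon as the exceedance count can no longer stay
// below alpha.
//
// The statistic for an arc of length l with sum X in a stretch of length n
// and total sum s is |X - l*s/n| / sqrt(p(1-p) * l * (n-l) / n), p = s/n:
// the standardized difference in proportions between arc and complement.
// The R-level exhaustive oracle mirrors this expression operation by
// operation so that tie-breaking is bit-identical.
//
// The permutation scan exploits a monotonicity property of binary data:
// both the maximum and the minimum window sum over starts are
// nondecreasing in the window length, with increments of at most 1. After
// an exact evaluation at length l the scan can therefore jump directly to
// the next length at which an exceedance is arithmetically possible,
// which prunes almost all lengths when the observed statistic is large.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct ArcBest {
  double z;   // maximal statistic over all arcs (any start)
  int i;      // chosen arc start (piece-width-admissible), -1 if none
  int l;      // chosen arc length
};

// Maximal statistic over all arcs with l in [minw, n-minw] and any start,
// plus the best piece-width-admissible arc (pieces of width 0 or >= minw)
// with ties broken by smallest start, then smallest length.
ArcBest max_arc_stat(const std::vector<int> &C, int n, int s, int minw) {
  ArcBest best = {0.0, -1, -1};
  if (n < 2 * minw || s == 0 || s == n) return best;
  double p = (double)s / n;
  double pq = p * (1.0 - p);
  for (int l = minw; l <= n - minw; ++l) {
    double mu = (double)l * s / n;
    double sd = std::sqrt(pq * (double)l * (double)(n - l) / n);
    int dmax = C[l] - C[0], dmin = dmax;
    for (int i = 1; i <= n - l; ++i) {
      int d = C[i + l] - C[i];
      if (d > dmax) dmax = d;
      else if (d < dmin) dmin = d;
    }
    double dev = (double)dmax - mu;
    double dev2 = mu - (double)dmin;
    if (dev2 > dev) dev = dev2;
    double z = dev / sd;
    if (z > best.z) best.z = z;
  }
  // admissible-arc resolution: best valid split, first in (i, l) order
  double zbest = 0.0;
  for (int i = 0; i <= n - minw; ++i) {
    if (i != 0 && i < minw) continue;
    for (int l = minw; i + l <= n && l <= n - minw; ++l) {
      int rest = n - i - l;
      if (rest != 0 && rest < minw) continue;
      double mu = (double)l * s / n;
      double sd = std::sqrt(pq * (double)l * (double)(n - l) / n);
      double z = std::fabs((double)(C[i + l] - C[i]) - mu) / sd;
      if (z > zbest) { zbest = z; best.i = i; best.l = l; }
    }
  }
  return best;
}

// TRUE if any arc of the (permuted) sequence reaches z >= zobs.
bool perm_exceeds(const std::vector<int> &C, int n, int s, int minw,
                  double zobs) {
  double p = (double)s / n;
  double pq = p * (1.0 - p);
  int lmax = n - minw;
  int l = minw;
  while (l <= lmax) {
    double mu = (double)l * s / n;
    double sd = std::sqrt(pq * (double)l * (double)(n - l) / n);
    double hi = mu + zobs * sd;
    double lo = mu - zobs * sd;
    int dmax = C[l] - C[0], dmin = dmax;
    for (int i = 1; i <= n - l; ++i) {
      int d = C[i + l] - C[i];
      if (d > dmax) dmax = d;
      else if (d < dmin) dmin = d;
    }
    if ((double)dmax >= hi || (double)dmin <= lo) return true;
    // jump: window extremes are nondecreasing in l with increments <= 1,
    // so at length l2 > l: dmax(l2) <= dmax + (l2-l), dmin(l2) >= dmin
    int l2 = l + 1;
    while (l2 <= lmax) {
      double mu2 = (double)l2 * s / n;
      double sd2 = std::sqrt(pq * (double)l2 * (double)(n - l2) / n);
      if ((double)dmax + (l2 - l) >= mu2 + zobs * sd2) break;
      if ((double)dmin <= mu2 - zobs * sd2) break;
      ++l2;
    }
    l = l2;
  }
  return false;
}

void cumsum01(const std::vector<int8_t> &y, int a, int n,
              std::vector<int> &C) {
  C[0] = 0;
  for (int k = 0; k < n; ++k) C[k + 1] = C[k] + y[a + k];
}

} // namespace

// [[Rcpp::export(name = ".cbs_binary_cpp")]]
List cbs_binary_cpp(IntegerVector x, double alpha, int nperm, int min_width,
                    int seed) {
  int n_all = x.size();
  std::vector<int8_t> y(n_all);
  for (int k = 0; k < n_all; ++k) y[k] = (int8_t)(x[k] != 0);

  std::mt19937_64 gen((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);
  std::vector<int> C(n_all + 1);
  std::vector<int8_t> yp(n_all);
  std::vector<int> bps;
  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, n_all});
  int n_tests = 0;
  int thresh = (int)std::ceil(alpha * nperm);
  if (thresh < 1) thresh = 1;

  while (!stack.empty()) {
    int a = stack.back().first, b = stack.back().second;
    stack.pop_back();
    int n = b - a;
    if (n < 2 * min_width) continue;
    cumsum01(y, a, n, C);
    int s = C[n];
    if (s == 0 || s == n) continue;
    ArcBest obs = max_arc_stat(C, n, s, min_width);
    if (obs.l < 0 || obs.i < 0 || obs.z <= 0) continue;
    ++n_tests;
    // permutation test with early rejection
    for (int k = 0; k < n; ++k) yp[k] = y[a + k];
    int exceed = 0;
    for (int perm = 0; perm < nperm; ++perm) {
      for (int k = n - 1; k >= 1; --k) {
        int j = (int)(gen() % (uint64_t)(k + 1));
        int8_t t = yp[k]; yp[k] = yp[j]; yp[j] = t;
      }
      C[0] = 0;
      for (int k = 0; k < n; ++k) C[k + 1] = C[k] + yp[k];
      if (perm_exceeds(C, n, s, min_width, obs.z)) ++exceed;
      if (exceed >= thresh) break;
    }
    if (exceed >= thresh) continue; // p-value >= alpha: no split
    int p1 = a + obs.i;
    int p2 = a + obs.i + obs.l;
    if (p1 > a) bps.push_back(p1);
    if (p2 < b) bps.push_back(p2);
    // recurse on the resulting pieces (LIFO, deterministic order)
    if (p2 < b) stack.push_back({p2, b});
    stack.push_back({p1 > a ? p1 : a, p2});
    if (p1 > a) stack.push_back({a, p1});
  }
  std::sort(bps.begin(), bps.end());
  return List::create(_["breakpoints"] = wrap(bps), _["n_tests"] = n_tests);
}

// [[Rcpp::export(name = ".max_arc_stat_cpp")]]
List max_arc_stat_cpp(IntegerVector x, int min_width) {
  int n = x.size();
  std::vector<int8_t> y(n);
  for (int k = 0; k < n; ++k) y[k] = (int8_t)(x[k] != 0);
  std::vector<int> C(n + 1);
  cumsum01(y, 0, n, C);
  int s = C[n];
  if (n < 2 * min_width || s == 0 || s == n)
    return List::create(_["stat"] = 0.0, _["start"] = NA_INTEGER,
                        _["end"] = NA_INTEGER);
  ArcBest best = max_arc_stat(C, n, s, min_width);
  return List::create(_["stat"] = best.z, _["start"] = best.i,
                      _["end"] = best.i + best.l);
}
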