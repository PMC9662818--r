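#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// auROC by sweeping a threshold over [min, max] of the pooled samples in
// `nsteps` equal steps (101 threshold values for the default 100 bins),
// plotting P(a > thr) against P(b > thr) and integrating by trapezoids with
// endpoint closure at (0,0) and (1,1).
//
// Both probability coordinates are non-increasing in the threshold, so the
// points traced from the highest threshold down to the lowest, bracketed by
// (0,0) and (1,1), are already ordered along the x axis.
static double auroc_sweep_impl(const std::vector<double>& a,
                               const std::vector<double>& b,
                               int nbins) {
  const int na = a.size(), nb = b.size();
  double lo = R_PosInf, hi = R_NegInf;
  for (double v : a) { lo = std::min(lo, v); hi = std::max(hi, v); }
  for (double v : b) { lo = std::min(lo, v); hi = std::max(hi, v); }
  if (!(hi > lo)) return 0.5;  // degenerate pooled range: no separation

  const int npts = nbins + 1;
  std::vector<double> px(npts + 2), py(npts + 2);
  px[0] = 0.0; py[0] = 0.0;
  const double step = (hi - lo) / nbins;
  for (int j = 0; j < npts; ++j) {
    const double thr = lo + (double)(nbins - j) * step;  // descending thresholds
    int ca = 0, cb = 0;
    for (double v : a) if (v > thr) ++ca;
    for (double v : b) if (v > thr) ++cb;
    px[j + 1] = (double) cb / nb;
    py[j + 1] = (double) ca / na;
  }
  px[npts + 1] = 1.0; py[npts + 1] = 1.0;

  double area = 0.0;
  for (int k = 0; k + 1 < npts + 2; ++k)
    area += (px[k + 1] - px[k]) * (py[k] + py[k + 1]) / 2.0;
  return area;
}

// Counting version used for the permutation null: the threshold grid is a
// function of the pooled samples only, so it is fixed across shuffles.  Each
// value is pre-assigned the number of grid thresholds strictly below it;
// cumulative tallies then give P(group > thr) for every threshold at O(n)
// per shuffle.
// [[Rcpp::export]]
double cpp_auroc_sweep(NumericVector a, NumericVector b, int nbins = 100) {
  return auroc_sweep_impl(as<std::vector<double>>(a),
                          as<std::vector<double>>(b), nbins);
}

// [[Rcpp::export]]
NumericVector cpp_shuffled_auroc(NumericVector pooled, int n_a, int n_shuffles,
                                 int nbins = 100) {
  const int n = pooled.size();
  const int nb = n - n_a;
  if (n_a < 1 || nb < 1) stop("both groups must be non-empty");
  double lo = R_PosInf, hi = R_NegInf;
  for (int i = 0; i < n; ++i) {
    lo = std::min(lo, pooled[i]);
    hi = std::max(hi, pooled[i]);
  }
  NumericVector out(n_shuffles);
  if (!(hi > lo)) { std::fill(out.begin(), out.end(), 0.5); return out; }

  const int npts = nbins + 1;
  const double step = (hi - lo) / nbins;
  // bin[i] = number of thresholds t_j = lo + j*step (j = 0..nbins) with
  // t_j < value i; value v exceeds thresholds 0..bin-1.
  std::vector<int> nbelow(n);
  for (int i = 0; i < n; ++i) {
    int k = (int) std::floor((pooled[i] - lo) / step);
    if (k > nbins) k = nbins;
    // correct for floating point: t_k may equal or exceed the value
    while (k >= 0 && lo + k * step >= pooled[i]) --k;
    while (k + 1 <= nbins && lo + (k + 1) * step < pooled[i]) ++k;
    nbelow[i] = k + 1;  // thresholds strictly below pooled[i]
  }

  std::vector<int> idx(n), counta(npts + 1), countb(npts + 1);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> px(npts + 2), py(npts + 2);

  for (int s = 0; s < n_shuffles; ++s) {
    // Fisher-Yates partial shuffle using R's RNG: first n_a entries -> group a
    for (int i = 0; i < n_a; ++i) {
      int j = i + (int) (unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
    }
    std::fill(counta.begin(), counta.end(), 0);
    std::fill(countb.begin(), countb.end(), 0);
    for (int i = 0; i < n_a; ++i) counta[nbelow[idx[i]]]++;
    for (int i = n_a; i < n; ++i) countb[nbelow[idx[i]]]++;
    // number of group members above threshold j = sum over k > j of count[k]
    int ca = 0, cb = 0;
    px[0] = 0.0; py[0] = 0.0;
    for (int j = npts - 1; j >= 0; --j) {
      // descending threshold order: j = npts-1 is the max threshold
      ca += counta[j + 1];
      cb += countb[j + 1];
      px[npts - j] = (double) cb / nb;
      py[npts - j] = (double) ca / n_a;
    }
    px[npts + 1] = 1.0; py[npts + 1] = 1.0;
    double area = 0.0;
    for (int k = 0; k + 1 < npts + 2; ++k)
      area += (px[k + 1] - px[k]) * (py[k] + py[k + 1]) / 2.0;
    out[s] = area;
  }
  return out;
}
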