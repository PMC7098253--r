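#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Helpers that keep the hot loops of simulation and event detection in
// compiled code: per-channel causal IIR filtering (one contiguous column
// per channel), negative-going threshold-crossing detection with per-window
// RMS thresholds and dead-time enforcement, spike-template insertion, and
// per-bin mean/RMS reduction.

// [[Rcpp::export(name = ".iir_filter_cols_cpp")]]
NumericMatrix iir_filter_cols_cpp(NumericVector b, NumericVector a,
                                  NumericMatrix x) {
  const int nb = b.size(), na = a.size();
  const R_xlen_t n = x.nrow();
  const int nch = x.ncol();
  if (na < 1 || a[0] == 0) stop("a[0] must be non-zero");
  const int nw = std::max(nb, na) - 1;
  std::vector<double> bb(nw + 1, 0.0), aa(nw + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  NumericMatrix y(n, nch);
  std::vector<double> w(nw);
  for (int ch = 0; ch < nch; ++ch) {
    const double *xc = &x[(R_xlen_t)ch * n];
    double *yc = &y[(R_xlen_t)ch * n];
    std::fill(w.begin(), w.end(), 0.0);
    for (R_xlen_t t = 0; t < n; ++t) {
      const double xt = xc[t];
      const double yt = bb[0] * xt + (nw > 0 ? w[0] : 0.0);
      for (int i = 0; i < nw - 1; ++i)
        w[i] = bb[i + 1] * xt - aa[i + 1] * yt + w[i + 1];
      if (nw > 0) w[nw - 1] = bb[nw] * xt - aa[nw] * yt;
      yc[t] = yt;
    }
  }
  return y;
}

// Negative-going crossings of (multiplier x per-window RMS), dead time in
// samples enforced across window joins. Returns 1-based sample indices and
// the per-window thresholds.
// [[Rcpp::export(name = ".detect_crossings_cpp")]]
List detect_crossings_cpp(NumericVector x, int wlen, double multiplier,
                          int dead) {
  const R_xlen_t n = x.size();
  const int nwin = (int)((n + wlen - 1) / wlen);
  NumericVector thr(nwin);
  std::vector<int> idx;
  R_xlen_t last = -2 * (R_xlen_t)std::max(dead, 1);
  for (int wi = 0; wi < nwin; ++wi) {
    const R_xlen_t lo = (R_xlen_t)wi * wlen;
    const R_xlen_t hi = std::min(lo + wlen, n);
    double ss = 0.0;
    for (R_xlen_t t = lo; t < hi; ++t) ss += x[t] * x[t];
    const double th = multiplier * std::sqrt(ss / (double)(hi - lo));
    thr[wi] = th;
    for (R_xlen_t t = std::max(lo, (R_xlen_t)1); t < hi; ++t) {
      if (x[t] < th && x[t - 1] >= th && t - last >= dead) {
        idx.push_back((int)t + 1);
        last = t;
      }
    }
  }
  return List::create(_["idx"] = wrap(idx), _["thr"] = thr);
}

// Adds amp * w so that w's reference sample (peak_at, 1-based) lands on each
// spike's 1-based sample index, into column `ch` (1-based) of the
// samples x channels matrix, in place.
// [[Rcpp::export(name = ".add_spikes_cpp")]]
void add_spikes_cpp(NumericMatrix samples, int ch, IntegerVector peak_idx,
                    NumericVector w, int peak_at, double amp) {
  const R_xlen_t n = samples.nrow();
  const int L = w.size();
  double *col = &samples[(R_xlen_t)(ch - 1) * n];
  for (int k = 0; k < peak_idx.size(); ++k) {
    const R_xlen_t i0 = (R_xlen_t)peak_idx[k] - peak_at; // 0-based start
    for (int j = 0; j < L; ++j) {
      const R_xlen_t t = i0 + j;
      if (t >= 0 && t < n) col[t] += amp * w[j];
    }
  }
}

// Per-bin reduction of every channel: op 0 = mean, 1 = RMS. Trailing
// partial bins are dropped by the caller (n_bins * bin_len <= n_samples).
// [[Rcpp::export(name = ".bin_reduce_cpp")]]
NumericMatrix bin_reduce_cpp(NumericMatrix x, int bin_len, int n_bins,
                             int op) {
  const R_xlen_t n = x.nrow();
  const int nch = x.ncol();
  if ((R_xlen_t)bin_len * n_bins > n) stop("bins exceed the recording");
  NumericMatrix out(n_bins, nch);
  for (int ch = 0; ch < nch; ++ch) {
    const double *xc = &x[(R_xlen_t)ch * n];
    for (int b = 0; b < n_bins; ++b) {
      const double *seg = xc + (R_xlen_t)b * bin_len;
      double s = 0.0;
      if (op == 0) for (int j = 0; j < bin_len; ++j) s += seg[j];
      else for (int j = 0; j < bin_len; ++j) s += seg[j] * seg[j];
      out(b, ch) = op == 0 ? s / bin_len : std::sqrt(s / bin_len);
    }
  }
  return out;
}
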