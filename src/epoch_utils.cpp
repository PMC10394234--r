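#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-trial artifact statistics on an epochs array (nsamp x ntrial x nch,
// column-major). Column 1: max |x| over the EEG channels; column 2:
// peak-to-peak amplitude on the EOG channel (0 if eog < 1).
// [[Rcpp::export]]
NumericMatrix cpp_trial_stats(NumericVector trials, int nsamp, int ntrial,
                              int nch, IntegerVector eeg, int eog) {
  NumericMatrix out(ntrial, 2);
  const double *p = REAL(trials);
  const R_xlen_t plane = (R_xlen_t)nsamp * ntrial;
  for (int t = 0; t < ntrial; ++t) {
    double amax = 0.0;
    for (int k = 0; k < eeg.size(); ++k) {
      const double *col = p + (R_xlen_t)(eeg[k] - 1) * plane +
                          (R_xlen_t)t * nsamp;
      for (int s = 0; s < nsamp; ++s) {
        double a = std::fabs(col[s]);
        if (a > amax) amax = a;
      }
    }
    out(t, 0) = amax;
    if (eog >= 1) {
      const double *col = p + (R_xlen_t)(eog - 1) * plane +
                          (R_xlen_t)t * nsamp;
      double lo = col[0], hi = col[0];
      for (int s = 1; s < nsamp; ++s) {
        if (col[s] < lo) lo = col[s];
        if (col[s] > hi) hi = col[s];
      }
      out(t, 1) = hi - lo;
    }
  }
  return out;
}

// Mean over the selected trials (1-based indices) of an epochs array.
// Returns nsamp x nch.
// [[Rcpp::export]]
NumericMatrix cpp_cond_mean(NumericVector trials, int nsamp, int ntrial,
                            int nch, IntegerVector sel) {
  NumericMatrix out(nsamp, nch);
  const double *p = REAL(trials);
  const R_xlen_t plane = (R_xlen_t)nsamp * ntrial;
  const double w = 1.0 / sel.size();
  for (int c = 0; c < nch; ++c) {
    double *o = &out(0, c);
    for (int k = 0; k < sel.size(); ++k) {
      const double *col = p + (R_xlen_t)c * plane +
                          (R_xlen_t)(sel[k] - 1) * nsamp;
      for (int s = 0; s < nsamp; ++s) o[s] += col[s];
    }
    for (int s = 0; s < nsamp; ++s) o[s] *= w;
  }
  return out;
}

// Accumulate a template (tlen x nch) into data (n x nch) at the given
// 1-based onset samples, scaled per event. Modifies data in place.
// [[Rcpp::export]]
void cpp_add_events(NumericMatrix data, NumericMatrix tpl,
                    IntegerVector onsets, NumericVector scale) {
  const int n = data.nrow(), nch = data.ncol(), tlen = tpl.nrow();
  for (int c = 0; c < nch; ++c) {
    double *d = &data(0, c);
    const double *tp = &tpl(0, c);
    for (int e = 0; e < onsets.size(); ++e) {
      const int o = onsets[e] - 1;
      const double sc = scale[e];
      const int lim = std::min(tlen, n - o);
      for (int s = 0; s < lim; ++s) d[o + s] += sc * tp[s];
    }
  }
}
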