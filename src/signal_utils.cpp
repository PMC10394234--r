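// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Zero-phase frequency-domain filtering of a real samples x channels
// matrix with the (real, even) transfer function H of length nfft >= n.
// Channel pairs are packed into complex columns so half the FFTs suffice.
// [[Rcpp::export]]
arma::mat cpp_fft_filter(const arma::mat& X, const arma::vec& H) {
  const uword n = X.n_rows, nc = X.n_cols;
  const uword nfft = H.n_elem;
  const uword npair = nc / 2;
  mat out(n, nc);
  if (npair > 0) {
    mat re(nfft, npair, fill::zeros), im(nfft, npair, fill::zeros);
    re.rows(0, n - 1) = X.cols(0, npair - 1);
    im.rows(0, n - 1) = X.cols(npair, 2 * npair - 1);
    cx_mat Z(re, im);
    Z = fft(Z);
    Z.each_col() %= conv_to<cx_vec>::from(H);
    Z = ifft(Z);
    out.cols(0, npair - 1) = real(Z.rows(0, n - 1));
    out.cols(npair, 2 * npair - 1) = imag(Z.rows(0, n - 1));
  }
  if (nc % 2 == 1) {
    cx_vec z(nfft, fill::zeros);
    z.head(n) = conv_to<cx_vec>::from(X.col(nc - 1));
    z = fft(z);
    z %= conv_to<cx_vec>::from(H);
    z = ifft(z);
    out.col(nc - 1) = real(z.head(n));
  }
  return out;
}

// Inverse FFT of band-limited complex spectra given only the non-zero bins
// (1-based row indices into an nfft-long spectrum); returns [Re | Im] of
// the first n samples of each column (two independent real signals per
// complex column).
// [[Rcpp::export]]
arma::mat cpp_spectrum_to_noise(const arma::cx_mat& Zband,
                                const arma::uvec& bins, int nfft, int n) {
  cx_mat Z(nfft, Zband.n_cols, fill::zeros);
  Z.rows(bins - 1) = Zband;
  cx_mat y = ifft(Z);
  mat out(n, 2 * Zband.n_cols);
  out.cols(0, Zband.n_cols - 1) = real(y.rows(0, n - 1));
  out.cols(Zband.n_cols, 2 * Zband.n_cols - 1) = imag(y.rows(0, n - 1));
  return out;
}

// Subtract the row-wise mean of the `eeg` columns (1-based indices) from
// those columns, leaving the others untouched.
// [[Rcpp::export]]
arma::mat cpp_subtract_rowmean(const arma::mat& X, const arma::uvec& eeg) {
  mat out = X;
  uvec idx = eeg - 1;
  const uword n = out.n_rows, ne = idx.n_elem;
  vec m(n, fill::zeros);
  for (uword k = 0; k < ne; ++k) {
    const double *c = out.colptr(idx[k]);
    double *mp = m.memptr();
    for (uword s = 0; s < n; ++s) mp[s] += c[s];
  }
  m /= (double)ne;
  for (uword k = 0; k < ne; ++k) {
    double *c = out.colptr(idx[k]);
    const double *mp = m.memptr();
    for (uword s = 0; s < n; ++s) c[s] -= mp[s];
  }
  return out;
}

// Cut epochs around 1-based onset samples and subtract the per-trial,
// per-channel baseline (mean of the first npre samples). Trials whose
// window exceeds the data range are left as zeros (flagged by the caller).
// Returns an (npre+npost) x ntrial x nch array.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_segment(const arma::mat& X,
                                const arma::ivec& onsets,
                                int npre, int npost,
                                const arma::ivec& ok) {
  const int nsamp = npre + npost;
  const uword ntr = onsets.n_elem, nch = X.n_cols;
  Rcpp::NumericVector out((R_xlen_t)nsamp * ntr * nch);
  double *o = REAL(out);
  for (uword c = 0; c < nch; ++c) {
    const double *col = X.colptr(c);
    for (uword t = 0; t < ntr; ++t) {
      double *dst = o + ((R_xlen_t)c * ntr + t) * nsamp;
      if (!ok[t]) continue;
      const double *src = col + (onsets[t] - 1) - npre;
      double bl = 0.0;
      for (int s = 0; s < npre; ++s) bl += src[s];
      bl /= npre;
      for (int s = 0; s < nsamp; ++s) dst[s] = src[s] - bl;
    }
  }
  out.attr("dim") = Rcpp::IntegerVector::create(nsamp, (int)ntr, (int)nch);
  return out;
}
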