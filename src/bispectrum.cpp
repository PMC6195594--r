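// Direct-FFT bispectrum accumulation. The (f1, f2) grid is O(nfft^2) and
// the accumulation runs over every averaging segment, which is too hot a
// loop for interpreted code at 30-s windows x channels x seizures scale.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// segs: seg_len x K matrix of real-valued segments (columns).
// taper: length seg_len window function (all ones for "none").
// Returns the (nfft/2+1) x (nfft/2+1) complex matrix
//   B(i, j) = (1/K) sum_k X_k(i) X_k(j) conj(X_k(i+j))
// with X_k the FFT of the (optionally mean-subtracted) tapered segment,
// scaled by 1/seg_len. Bins with i + j > nfft/2 are outside the support of
// the estimate for a real signal's principal region and are left at zero.
// [[Rcpp::export]]
arma::cx_mat bispec_direct_cpp(const arma::mat& segs, const arma::vec& taper,
                               bool mean_subtract) {
  const uword n = segs.n_rows, K = segs.n_cols, n2 = n / 2;
  cx_mat B(n2 + 1, n2 + 1, fill::zeros);
  for (uword k = 0; k < K; ++k) {
    vec x = segs.col(k);
    if (mean_subtract) x -= mean(x);
    x %= taper;
    cx_vec X = fft(x) / double(n);
    cx_vec Xc = conj(X);
    for (uword j = 0; j <= n2; ++j) {
      const cx_double Xj = X(j);
      for (uword i = j; i + j <= n2; ++i) {
        B(i, j) += X(i) * Xj * Xc(i + j);
      }
    }
  }
  B /= double(K);
  // symmetry under f1 <-> f2
  for (uword j = 0; j <= n2; ++j)
    for (uword i = j; i <= n2; ++i)
      B(j, i) = B(i, j);
  return B;
}

// Fused per-window feature path: same estimate as bispec_direct_cpp but
// reduced in place to (Mave, P1, P2) over the principal-domain bins given
// as 0-based column-major indices into the (n2+1) x (n2+1) grid. Avoids
// materializing the full complex matrix in R once per window x channel.
// [[Rcpp::export]]
arma::vec bispec_features_cpp(const arma::mat& segs, const arma::vec& taper,
                              bool mean_subtract, const arma::uvec& mask_idx) {
  const uword n = segs.n_rows, K = segs.n_cols, n2 = n / 2;
  cx_mat B(n2 + 1, n2 + 1, fill::zeros);
  for (uword k = 0; k < K; ++k) {
    vec x = segs.col(k);
    if (mean_subtract) x -= mean(x);
    x %= taper;
    cx_vec X = fft(x) / double(n);
    cx_vec Xc = conj(X);
    for (uword j = 0; j <= n2; ++j) {
      const cx_double Xj = X(j);
      for (uword i = j; i + j <= n2; ++i) {
        B(i, j) += X(i) * Xj * Xc(i + j);
      }
    }
  }
  B /= double(K);
  const uword L = mask_idx.n_elem;
  double s1 = 0, s2 = 0, h1 = 0, h2 = 0;
  vec m(L);
  for (uword u = 0; u < L; ++u) {
    m(u) = std::abs(B(mask_idx(u)));
    s1 += m(u);
    s2 += m(u) * m(u);
  }
  vec out(3);
  if (s1 <= 0 || !std::isfinite(s1)) {
    out.fill(datum::nan);
    out(0) = s1 / double(L);
    return out;
  }
  for (uword u = 0; u < L; ++u) {
    if (m(u) > 0) {
      h1 += m(u) * std::log(m(u));
      h2 += m(u) * m(u) * std::log(m(u) * m(u));
    }
  }
  out(0) = s1 / double(L);                  // Mave
  out(1) = std::log(s1) - h1 / s1;          // P1 = -sum p log p
  out(2) = std::log(s2) - h2 / s2;          // P2
  return out;
}
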