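// Distance-correlation kernels.
//
// The lag-maximised distance correlation and its circular-rotation surrogate
// null both need dCor(x, rotate(y, k)) for many rotations k of the same pair.
// Rotating y permutes its pairwise-distance matrix by the same index shift on
// rows and columns, and U/V double-centering commutes with simultaneous
// row/column permutation, so the double-centered matrices A (from x) and B
// (from y) can be computed once.  The rotated distance covariance
//   S(k) = (1/n^2) * sum_{i,j} A[i,j] * B[i+k, j+k]   (indices mod n)
// is a sum over circular diagonals of cross-correlations, which an FFT per
// diagonal evaluates for every k at once in O(n^2 log n) instead of O(n^3).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat centered_absdiff(const vec& x) {
  const uword n = x.n_elem;
  mat A(n, n);
  for (uword j = 0; j < n; ++j)
    for (uword i = 0; i < n; ++i)
      A(i, j) = std::abs(x[i] - x[j]);
  rowvec cm = mean(A, 0);
  vec    rm = mean(A, 1);
  double gm = mean(cm);
  A.each_row() -= cm;
  A.each_col() -= rm;
  A += gm;
  return A;
}

// dCor(x, rotate(y, k)) for k = 0..n-1, where rotate(y, k)[t] = y[t + k]
// (circular).  Returns the zero vector when either series is constant; the
// R caller raises the degenerate-variance error.
// [[Rcpp::export]]
Rcpp::NumericVector dcor_rotation_profile_cpp(const arma::vec& x,
                                              const arma::vec& y) {
  const uword n = x.n_elem;
  mat A = centered_absdiff(x);
  mat B = centered_absdiff(y);
  double vx = accu(A % A) / double(n * n);
  double vy = accu(B % B) / double(n * n);
  Rcpp::NumericVector out(n);
  if (vx <= 0.0 || vy <= 0.0) return out;
  double denom = std::sqrt(std::sqrt(vx * vy));

  // Arrange circular diagonals as columns: Ad(i, d) = A(i, (i + d) mod n).
  mat Ad(n, n), Bd(n, n);
  for (uword d = 0; d < n; ++d)
    for (uword i = 0; i < n; ++i) {
      uword j = i + d; if (j >= n) j -= n;
      Ad(i, d) = A(i, j);
      Bd(i, d) = B(i, j);
    }
  cx_mat Fa = fft(Ad), Fb = fft(Bd);
  cx_vec Sf = sum(conj(Fa) % Fb, 1);
  vec S = real(ifft(Sf)) / double(n * n);  // dCov^2 per rotation

  for (uword k = 0; k < n; ++k)
    out[k] = std::sqrt(std::max(S[k], 0.0)) / denom;
  return out;
}

// Plain dCor for a single pair (same V-statistic as profile position 0).
// [[Rcpp::export]]
double dcor_cpp(const arma::vec& x, const arma::vec& y) {
  const uword n = x.n_elem;
  mat A = centered_absdiff(x);
  mat B = centered_absdiff(y);
  double vx = accu(A % A) / double(n * n);
  double vy = accu(B % B) / double(n * n);
  if (vx <= 0.0 || vy <= 0.0) return NA_REAL;
  double dcov2 = accu(A % B) / double(n * n);
  return std::sqrt(std::max(dcov2, 0.0)) / std::sqrt(std::sqrt(vx * vy));
}
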