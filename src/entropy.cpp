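#include <Rcpp.h>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Template-matching kernels for regularity/complexity statistics on
// physiological time series. Quadratic loops live here because segment
// lengths (~10^3) make the O(n^2) match counts the pipeline hot spot.

// Are the length-m templates at i and j within Chebyshev distance r?
// Early exit on the first coordinate exceeding r (the common case for
// the data-relative tolerances in use).
static inline bool within(const double* x, int i, int j, int m, double r) {
  for (int k = 0; k < m; ++k)
    if (std::fabs(x[i + k] - x[j + k]) > r) return false;
  return true;
}

// Approximate entropy (Pincus): Phi_m(r) - Phi_{m+1}(r), with Phi the mean
// natural log of self-inclusive match fractions among the n-k+1 length-k
// templates. One symmetric pair scan fills the match counts for both
// template lengths: a length-(m+1) match requires the length-m match plus
// one extra coordinate.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("series too short for embedding dimension m");
  if (r <= 0) stop("tolerance r must be positive");
  const double* px = REAL(x);
  int nt1 = n - m + 1;     // length-m templates
  int nt2 = n - m;         // length-(m+1) templates
  std::vector<int> c1(nt1, 1), c2(nt2, 1); // self-inclusive
  for (int i = 0; i < nt1 - 1; ++i) {
    for (int j = i + 1; j < nt1; ++j) {
      if (within(px, i, j, m, r)) {
        ++c1[i]; ++c1[j];
        if (j < nt2 && std::fabs(px[i + m] - px[j + m]) <= r) {
          ++c2[i]; ++c2[j];
        }
      }
    }
  }
  double phi1 = 0.0, phi2 = 0.0;
  for (int i = 0; i < nt1; ++i) phi1 += std::log((double)c1[i] / nt1);
  for (int i = 0; i < nt2; ++i) phi2 += std::log((double)c2[i] / nt2);
  return phi1 / nt1 - phi2 / nt2;
}

// Sample entropy (Richman & Moorman): -ln(A/B) with A, B the counts of
// length-(m+1) and length-m template pairs (i != j, both drawn from the
// first n-m templates) within tolerance r.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("series too short for embedding dimension m");
  if (r <= 0) stop("tolerance r must be positive");
  const double* px = REAL(x);
  int nt = n - m; // templates comparable at both lengths
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (within(px, i, j, m, r)) {
        ++B;
        if (std::fabs(px[i + m] - px[j + m]) <= r) ++A;
      }
    }
  }
  if (B == 0 || A == 0) return NA_REAL; // undefined: no template matches
  return -std::log((double)A / (double)B);
}

// LZ76 exhaustive-history parse count c(n) of a binary sequence
// (Lempel & Ziv 1976, via the Kaspar & Schuster scan).
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n < 2) stop("sequence too short");
  const int* b = INTEGER(s);
  int c = 1;       // first symbol is always a new word
  int i = 0;       // start of current history prefix comparison
  int k = 1;       // current extension length
  int l = 1;       // start of the word being parsed
  int kmax = 1;
  while (true) {
    if (b[i + k - 1] == b[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) { // no history match extends: close the word
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
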