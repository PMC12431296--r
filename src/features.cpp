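#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// db4 decomposition low-pass filter (8 taps, orthonormal).
static const double DB4_LO[8] = {
    -0.010597401784997278,  0.032883011666982945,
     0.030841381835986965, -0.187034811718881140,
    -0.027983769416983850,  0.630880767929590400,
     0.714846570552541500,  0.230377813308855230};

// One periodized analysis step: x (length n, n even) -> approx a, detail d
// (length n/2 each). Quadrature mirror: g[k] = (-1)^k lo[L-1-k].
static void dwt_step(const std::vector<double>& x,
                     std::vector<double>& a, std::vector<double>& d) {
  const int n = (int)x.size(), half = n / 2, L = 8;
  a.assign(half, 0.0);
  d.assign(half, 0.0);
  for (int k = 0; k < half; ++k) {
    double sa = 0.0, sd = 0.0;
    for (int j = 0; j < L; ++j) {
      double xv = x[(2 * k + j) % n];
      sa += DB4_LO[j] * xv;
      sd += ((j % 2) ? -1.0 : 1.0) * DB4_LO[L - 1 - j] * xv;
    }
    a[k] = sa;
    d[k] = sd;
  }
}

// Full wavelet-packet decomposition of x to `levels` levels (periodized
// db4). Returns the 2^levels leaf energies (sum of squared coefficients)
// in frequency order, so leaf b covers [b, b+1) * fs / 2^(levels+1) Hz.
// [[Rcpp::export]]
NumericVector wpd_leaf_energies_cpp(NumericVector x, int levels) {
  int n = x.size();
  if (levels < 1) stop("levels must be >= 1");
  if (n < (1 << levels)) stop("signal shorter than 2^levels samples");
  // Pad to a multiple of 2^levels with zeros so every split halves evenly;
  // zero padding preserves total energy of the periodized transform only
  // approximately, so callers wanting exact Parseval should pass lengths
  // divisible by 2^levels.
  int block = 1 << levels;
  int npad = ((n + block - 1) / block) * block;
  std::vector<double> x0(npad, 0.0);
  for (int i = 0; i < n; ++i) x0[i] = x[i];

  // nodes in natural order with their frequency index
  std::vector<std::vector<double> > nodes;
  std::vector<int> freq;
  nodes.push_back(x0);
  freq.push_back(0);
  for (int lev = 0; lev < levels; ++lev) {
    std::vector<std::vector<double> > nxt;
    std::vector<int> nfreq;
    for (size_t i = 0; i < nodes.size(); ++i) {
      std::vector<double> a, d;
      dwt_step(nodes[i], a, d);
      int f = freq[i];
      // high-pass child is spectrally reversed when parent band index is odd
      if (f % 2 == 0) {
        nxt.push_back(a); nfreq.push_back(2 * f);
        nxt.push_back(d); nfreq.push_back(2 * f + 1);
      } else {
        nxt.push_back(a); nfreq.push_back(2 * f + 1);
        nxt.push_back(d); nfreq.push_back(2 * f);
      }
    }
    nodes.swap(nxt);
    freq.swap(nfreq);
  }
  NumericVector out(1 << levels);
  for (size_t i = 0; i < nodes.size(); ++i) {
    double e = 0.0;
    for (size_t k = 0; k < nodes[i].size(); ++k) e += nodes[i][k] * nodes[i][k];
    out[freq[i]] = e;
  }
  return out;
}

// Template-match counts for sample entropy: B pairs agree over m points,
// A pairs over m+1, Chebyshev distance <= r, pairs i < j drawn from the
// N - m template start positions (self-matches excluded by i < j).
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) stop("series too short for embedding dimension m");
  long long A = 0, B = 0;
  int nt = n - m;  // templates of length m+1 start at 0..n-m-1 too
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
    }
  }
  return List::create(Named("A") = (double)A, Named("B") = (double)B);
}

// Higuchi average curve lengths L(k) for k = 1..kmax.
// [[Rcpp::export]]
NumericVector higuchi_lengths_cpp(NumericVector x, int kmax) {
  int n = x.size();
  if (n <= kmax) stop("series must be longer than kmax");
  NumericVector L(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    for (int m = 0; m < k; ++m) {
      int nm = (n - 1 - m) / k;  // number of increments
      if (nm < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= nm; ++i)
        s += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      // normalisation maps the subsampled length back to the full grid
      Lk += s * (double)(n - 1) / ((double)nm * k * k);
    }
    L[k - 1] = Lk / k;
  }
  return L;
}
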