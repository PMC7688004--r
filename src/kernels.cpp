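// String-kernel dynamic programming: Smith-Waterman affine-gap local
// alignment score, local-alignment (sum-over-alignments) kernel in log
// space, and the (k,m)-mismatch kernel via pairwise k-mer comparison.
//
// Sequences arrive as 0-based integer vectors over the 20-letter alphabet.
// Gap convention: a gap of length L costs open + (L - 1) * extend.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp((a < b ? a : b) - m));
}

// Optimal local-alignment score (Smith-Waterman, affine gaps).
static double sw_pair(const std::vector<int>& a, const std::vector<int>& b,
                      const NumericMatrix& sub, double open, double ext) {
  const int n = a.size(), m = b.size();
  std::vector<double> M(m + 1, NEG_INF), X(m + 1, NEG_INF), Y(m + 1, NEG_INF);
  std::vector<double> Mprev(m + 1, NEG_INF), Xprev(m + 1, NEG_INF), Yprev(m + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::swap(M, Mprev); std::swap(X, Xprev); std::swap(Y, Yprev);
    M[0] = X[0] = Y[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      double prev = 0.0;
      if (Mprev[j - 1] > prev) prev = Mprev[j - 1];
      if (Xprev[j - 1] > prev) prev = Xprev[j - 1];
      if (Yprev[j - 1] > prev) prev = Yprev[j - 1];
      M[j] = s + prev;
      double x1 = (Mprev[j] == NEG_INF) ? NEG_INF : Mprev[j] - open;
      double x2 = (Xprev[j] == NEG_INF) ? NEG_INF : Xprev[j] - ext;
      X[j] = x1 > x2 ? x1 : x2;
      double y1 = (M[j - 1] == NEG_INF) ? NEG_INF : M[j - 1] - open;
      double y2 = (X[j - 1] == NEG_INF) ? NEG_INF : X[j - 1] - open;
      double y3 = (Y[j - 1] == NEG_INF) ? NEG_INF : Y[j - 1] - ext;
      Y[j] = std::max(y1, std::max(y2, y3));
      if (M[j] > best) best = M[j];
    }
  }
  return best;
}

// log of the local-alignment kernel: log sum over all local alignments
// (including the empty one) of exp(beta * score).
static double la_pair_log(const std::vector<int>& a, const std::vector<int>& b,
                          const NumericMatrix& sub, double open, double ext,
                          double beta) {
  const int n = a.size(), m = b.size();
  const double go = beta * open, ge = beta * ext;
  std::vector<double> M(m + 1, NEG_INF), X(m + 1, NEG_INF), Y(m + 1, NEG_INF);
  std::vector<double> Mprev(m + 1, NEG_INF), Xprev(m + 1, NEG_INF), Yprev(m + 1, NEG_INF);
  double acc = NEG_INF;  // log sum of all M(i, j)
  for (int i = 1; i <= n; ++i) {
    std::swap(M, Mprev); std::swap(X, Xprev); std::swap(Y, Yprev);
    M[0] = X[0] = Y[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double s = beta * sub(a[i - 1], b[j - 1]);
      double prev = lse2(0.0, lse2(Mprev[j - 1], lse2(Xprev[j - 1], Yprev[j - 1])));
      M[j] = s + prev;
      X[j] = lse2(Mprev[j] - go, Xprev[j] - ge);
      Y[j] = lse2(lse2(M[j - 1] - go, X[j - 1] - go), Y[j - 1] - ge);
      acc = lse2(acc, M[j]);
    }
  }
  return lse2(0.0, acc);  // the empty alignment contributes exp(0)
}

// Mismatch kernel via the pair-count identity: the contribution of a k-mer
// pair depends only on its Hamming distance d; `pair_counts[d]` is the
// number of k-mers u within distance m of both members of such a pair.
static double mm_pair(const std::vector<int>& a, const std::vector<int>& b,
                      int k, const NumericVector& pair_counts) {
  const int na = (int)a.size() - k + 1, nb = (int)b.size() - k + 1;
  double total = 0.0;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      int d = 0;
      for (int t = 0; t < k; ++t) d += (a[i + t] != b[j + t]);
      total += pair_counts[d];
    }
  }
  return total;
}

static std::vector<std::vector<int>> to_int_seqs(const List& seqs) {
  std::vector<std::vector<int>> out;
  out.reserve(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector v = seqs[i];
    out.emplace_back(v.begin(), v.end());
  }
  return out;
}

// [[Rcpp::export]]
NumericVector sw_kernel_cpp(List a, List b, NumericMatrix sub,
                            double open, double ext) {
  auto A = to_int_seqs(a), B = to_int_seqs(b);
  NumericVector out(A.size());
  for (size_t i = 0; i < A.size(); ++i) out[i] = sw_pair(A[i], B[i], sub, open, ext);
  return out;
}

// [[Rcpp::export]]
NumericVector la_kernel_log_cpp(List a, List b, NumericMatrix sub,
                                double open, double ext, double beta) {
  auto A = to_int_seqs(a), B = to_int_seqs(b);
  NumericVector out(A.size());
  for (size_t i = 0; i < A.size(); ++i)
    out[i] = la_pair_log(A[i], B[i], sub, open, ext, beta);
  return out;
}

// [[Rcpp::export]]
NumericVector mismatch_kernel_cpp(List a, List b, int k, NumericVector pair_counts) {
  auto A = to_int_seqs(a), B = to_int_seqs(b);
  NumericVector out(A.size());
  for (size_t i = 0; i < A.size(); ++i)
    out[i] = mm_pair(A[i], B[i], k, pair_counts);
  return out;
}

// Symmetric or rectangular Gram matrix over sequence lists.
// kernel: 0 = SW, 1 = LA (linear-space value), 2 = mismatch.
// [[Rcpp::export]]
NumericMatrix gram_cpp(List a, List b, bool symmetric, int kernel,
                       NumericMatrix sub, double open, double ext,
                       double beta, int k, NumericVector pair_counts) {
  auto A = to_int_seqs(a), B = to_int_seqs(b);
  NumericMatrix out(A.size(), B.size());
  for (size_t i = 0; i < A.size(); ++i) {
    size_t j0 = symmetric ? i : 0;
    for (size_t j = j0; j < B.size(); ++j) {
      double v;
      if (kernel == 0) v = sw_pair(A[i], B[j], sub, open, ext);
      else if (kernel == 1) v = std::exp(la_pair_log(A[i], B[j], sub, open, ext, beta));
      else v = mm_pair(A[i], B[j], k, pair_counts);
      out(i, j) = v;
      if (symmetric) out(j, i) = v;
    }
  }
  return out;
}
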