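#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman score (Gotoh recurrences, score only).
// Gap convention matches the R side: a gap of length L costs
// gap_open + (L - 1) * gap_extend, both penalties negative.
// Sequences arrive integer-encoded as 0-based rows/columns of submat.
static double sw_score_one(const int* q, int n, const int* s, int m,
                           const double* sub, int stride, double gap_open,
                           double gap_extend, std::vector<double>& M,
                           std::vector<double>& Ix, std::vector<double>& Iy,
                           std::vector<double>& Mprev,
                           std::vector<double>& Ixprev,
                           std::vector<double>& Iyprev) {
  const double NEG = -1e30;
  std::fill(Mprev.begin(), Mprev.begin() + m + 1, NEG);
  std::fill(Ixprev.begin(), Ixprev.begin() + m + 1, NEG);
  std::fill(Iyprev.begin(), Iyprev.begin() + m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG;
    Ix[0] = NEG;
    Iy[0] = NEG;
    const double* subrow = sub + (size_t)q[i - 1]; // column-major: row offset
    for (int j = 1; j <= m; ++j) {
      double diag = Mprev[j - 1];
      if (Ixprev[j - 1] > diag) diag = Ixprev[j - 1];
      if (Iyprev[j - 1] > diag) diag = Iyprev[j - 1];
      if (0.0 > diag) diag = 0.0;
      const double mj = subrow[(size_t)s[j - 1] * stride] + diag;
      M[j] = mj;
      const double ix = Mprev[j] + gap_open;
      const double ix2 = Ixprev[j] + gap_extend;
      Ix[j] = ix > ix2 ? ix : ix2;
      const double iy = M[j - 1] + gap_open;
      const double iy2 = Iy[j - 1] + gap_extend;
      Iy[j] = iy > iy2 ? iy : iy2;
      if (mj > best) best = mj;
    }
    M.swap(Mprev);
    Ix.swap(Ixprev);
    Iy.swap(Iyprev);
  }
  return best;
}

// [[Rcpp::export]]
NumericVector sw_score_pairs(List seqs, IntegerVector i_idx,
                             IntegerVector j_idx, NumericMatrix submat,
                             double gap_open, double gap_extend) {
  const int n_pairs = i_idx.size();
  const int n_seqs = seqs.size();
  NumericVector out(n_pairs);
  std::vector<const int*> ptr(n_seqs);
  std::vector<int> len(n_seqs);
  std::vector<IntegerVector> keep(n_seqs); // protect from GC
  int max_len = 0;
  for (int k = 0; k < n_seqs; ++k) {
    keep[k] = seqs[k];
    ptr[k] = INTEGER(keep[k]);
    len[k] = keep[k].size();
    if (len[k] > max_len) max_len = len[k];
  }
  const double* sub = REAL(submat);
  const int stride = submat.nrow();
  std::vector<double> M(max_len + 1), Ix(max_len + 1), Iy(max_len + 1),
      Mprev(max_len + 1), Ixprev(max_len + 1), Iyprev(max_len + 1);
  for (int p = 0; p < n_pairs; ++p) {
    const int a = i_idx[p] - 1;
    const int b = j_idx[p] - 1;
    out[p] = sw_score_one(ptr[a], len[a], ptr[b], len[b], sub, stride,
                          gap_open, gap_extend, M, Ix, Iy, Mprev, Ixprev,
                          Iyprev);
  }
  return out;
}
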