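#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment score, linear gap penalty.
// Scoring fixed to the package's toy scheme: match +2, mismatch -1, gap -2.
static int sw_score_one(const std::string &a, const std::string &b) {
  const int match = 2, mismatch = -1, gap = -2;
  const size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = 0;
    const char ai = a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + (ai == b[j - 1] ? match : mismatch);
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      int v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0) v = 0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export]]
int sw_score_cpp(std::string a, std::string b) {
  return sw_score_one(a, b);
}

// All unordered pairs i < j (and optionally self), returned as a dense
// symmetric score matrix. Used by the synthetic all-vs-all search.
// [[Rcpp::export]]
IntegerMatrix sw_score_matrix_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = sw_score_one(s[i], s[i]);
    for (int j = i + 1; j < n; ++j) {
      int sc = sw_score_one(s[i], s[j]);
      out(i, j) = sc;
      out(j, i) = sc;
    }
  }
  return out;
}
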