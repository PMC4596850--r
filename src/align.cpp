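#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Needleman-Wunsch global alignment with linear gap penalty.
// Traceback preference on ties: diagonal > up (gap in b) > left (gap in a),
// which makes the reported alignment deterministic.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b,
              double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  // trace: 0 = diag, 1 = up, 2 = left
  std::vector<unsigned char> trace((n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; if (j) trace[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    trace[i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double sd = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double su = prev[j] + gap;
      double sl = cur[j - 1] + gap;
      double best = sd; unsigned char t = 0;
      if (su > best) { best = su; t = 1; }
      if (sl > best) { best = sl; t = 2; }
      cur[j] = best;
      trace[i * (m + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  double score = prev[m];
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = trace[i * (m + 1) + j];
    if (i > 0 && j > 0 && t == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (t == 1 || j == 0)) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  int matches = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] == rb[k] && ra[k] != '-') ++matches;
  return List::create(_["score"] = score,
                      _["aligned_a"] = ra,
                      _["aligned_b"] = rb,
                      _["matches"] = matches,
                      _["columns"] = (int) ra.size());
}

// Best ungapped overlap identity between two sequences at a fixed diagonal
// offset (b shifted by `offset` relative to a). 'N' never counts as a match.
// [[Rcpp::export(name = ".ungapped_identity")]]
List ungapped_identity(std::string a, std::string b, int offset) {
  const int n = a.size(), m = b.size();
  int start_a = std::max(0, offset);
  int start_b = std::max(0, -offset);
  int len = std::min(n - start_a, m - start_b);
  if (len <= 0)
    return List::create(_["identity"] = 0.0, _["overlap"] = 0);
  int matches = 0;
  for (int k = 0; k < len; ++k) {
    char ca = a[start_a + k], cb = b[start_b + k];
    if (ca == cb && ca != 'N') ++matches;
  }
  return List::create(_["identity"] = (double) matches / len,
                      _["overlap"] = len);
}
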