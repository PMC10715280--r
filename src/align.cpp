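#include <Rcpp.h>
#include <array>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Unrestricted Damerau-Levenshtein distance (Lowrance-Wagner): insertions,
// deletions, substitutions and adjacent transpositions, where transposed
// characters may take part in later edits. Unlike the restricted (OSA)
// recurrence this is a true metric.
static int dl_core(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  const int inf = n + m;
  std::vector<int> H((size_t)(n + 2) * (m + 2), 0);
  const int W = m + 2;
  H[0] = inf;
  for (int i = 0; i <= n; ++i) { H[(size_t)(i + 1) * W] = inf; H[(size_t)(i + 1) * W + 1] = i; }
  for (int j = 0; j <= m; ++j) { H[(size_t)j + 1] = inf; H[(size_t)W + j + 1] = j; }
  std::array<int, 256> da;
  da.fill(0);
  for (int i = 1; i <= n; ++i) {
    int db = 0;
    for (int j = 1; j <= m; ++j) {
      const int i1 = da[(unsigned char)b[j - 1]];
      const int j1 = db;
      int cost = 1;
      if (a[i - 1] == b[j - 1]) { cost = 0; db = j; }
      int best = std::min(H[(size_t)i * W + j] + cost,
                          std::min(H[(size_t)i * W + j + 1] + 1,
                                   H[(size_t)(i + 1) * W + j] + 1));
      best = std::min(best, H[(size_t)i1 * W + j1] + (i - i1 - 1) + 1 + (j - j1 - 1));
      H[(size_t)(i + 1) * W + j + 1] = best;
    }
    da[(unsigned char)a[i - 1]] = i;
  }
  return H[(size_t)(n + 1) * W + m + 1];
}

// [[Rcpp::export]]
IntegerVector dl_distance_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    String sa = a[k % a.size()], sb = b[k % b.size()];
    if (sa == NA_STRING || sb == NA_STRING) { out[k] = NA_INTEGER; continue; }
    out[k] = dl_core(std::string(sa.get_cstring()), std::string(sb.get_cstring()));
  }
  return out;
}

// Pairwise normalised DL distance: dl(a_i, b_j) / max(nchar(a_i), nchar(b_j)).
// Used for fuzzy token equivalence (threshold 0.2 = less than one error in
// five letters).
// [[Rcpp::export]]
NumericMatrix dl_ratio_matrix_cpp(CharacterVector a, CharacterVector b) {
  const int n = (int)a.size(), m = (int)b.size();
  NumericMatrix out(n, m);
  std::vector<std::string> av(n), bv(m);
  for (int i = 0; i < n; ++i) av[i] = std::string(String(a[i]).get_cstring());
  for (int j = 0; j < m; ++j) bv[j] = std::string(String(b[j]).get_cstring());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const int L = std::max((int)av[i].size(), (int)bv[j].size());
      out(i, j) = (L == 0) ? 0.0 : (double)dl_core(av[i], bv[j]) / (double)L;
    }
  }
  return out;
}

// Needleman-Wunsch global alignment over two sequences described only by
// their pairwise equivalence matrix eq (n x m). Linear gap penalty.
// Traceback tie-break: diagonal > gap-in-b (up) > gap-in-a (left), which
// makes the reported alignment deterministic.
// Returns score plus alignment columns as 1-based indices (0 = gap).
// [[Rcpp::export]]
List nw_align_eq_cpp(LogicalMatrix eq, double match, double mismatch, double gap) {
  const int n = eq.nrow(), m = eq.ncol();
  NumericMatrix H(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) H(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) H(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double d = H(i - 1, j - 1) + (eq(i - 1, j - 1) ? match : mismatch);
      const double u = H(i - 1, j) + gap;
      const double l = H(i, j - 1) + gap;
      H(i, j) = std::max(d, std::max(u, l));
    }
  }
  std::vector<int> ai, bj;
  int i = n, j = m;
  const double epsv = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(H(i, j) - (H(i - 1, j - 1) + (eq(i - 1, j - 1) ? match : mismatch))) < epsv) {
      ai.push_back(i); bj.push_back(j); --i; --j;
    } else if (i > 0 && std::abs(H(i, j) - (H(i - 1, j) + gap)) < epsv) {
      ai.push_back(i); bj.push_back(0); --i;
    } else {
      ai.push_back(0); bj.push_back(j); --j;
    }
  }
  const int k = (int)ai.size();
  IntegerMatrix cols(k, 2);
  for (int r = 0; r < k; ++r) {
    cols(r, 0) = ai[k - 1 - r];
    cols(r, 1) = bj[k - 1 - r];
  }
  return List::create(_["score"] = H(n, m), _["columns"] = cols);
}
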