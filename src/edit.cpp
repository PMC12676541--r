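#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Unit-cost Levenshtein distance, two-row dynamic programme.
static int lev(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j], cur[j - 1]) + 1);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector edit_dist_pair_cpp(CharacterVector s, CharacterVector t) {
  if (s.size() != t.size()) stop("s and t must have equal length");
  IntegerVector out(s.size());
  for (R_xlen_t i = 0; i < s.size(); ++i)
    out[i] = lev(as<std::string>(s[i]), as<std::string>(t[i]));
  return out;
}

// [[Rcpp::export]]
IntegerMatrix edit_dist_cross_cpp(CharacterVector q, CharacterVector b) {
  const R_xlen_t nq = q.size(), nb = b.size();
  std::vector<std::string> qs(nq), bs(nb);
  for (R_xlen_t i = 0; i < nq; ++i) qs[i] = as<std::string>(q[i]);
  for (R_xlen_t j = 0; j < nb; ++j) bs[j] = as<std::string>(b[j]);
  IntegerMatrix out(nq, nb);
  for (R_xlen_t i = 0; i < nq; ++i)
    for (R_xlen_t j = 0; j < nb; ++j)
      out(i, j) = lev(qs[i], bs[j]);
  return out;
}
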