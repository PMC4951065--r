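#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Base-pair stacking-free energy model: GC = -3, AU = -2, GU = -1 (wobble).
static inline double pairEnergy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 0.0;
}

// Nussinov-style minimum-energy folding. Pairs must enclose a hairpin loop of
// at least 3 unpaired bases; no pseudoknots. Energy of the empty structure is
// 0, so the optimum is always <= 0.
static double foldEnergy(const std::string& s) {
  const int n = (int)s.size();
  if (n < 5) return 0.0;
  std::vector<double> E((size_t)n * n, 0.0);
  for (int len = 5; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E[(size_t)i * n + (j - 1)];  // j unpaired
      for (int k = i; k <= j - 4; ++k) {
        double e = pairEnergy(s[k], s[j]);
        if (e < 0.0) {
          double left = (k > i) ? E[(size_t)i * n + (k - 1)] : 0.0;
          double inside = E[(size_t)(k + 1) * n + (j - 1)];
          double cand = left + e + inside;
          if (cand < best) best = cand;
        }
      }
      E[(size_t)i * n + j] = best;
    }
  }
  return E[(size_t)0 * n + (n - 1)];
}

// [[Rcpp::export(name = ".nussinovEnergy")]]
NumericVector nussinovEnergy(CharacterVector seqs) {
  const R_xlen_t n = seqs.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i])) {
      out[i] = NA_REAL;
      continue;
    }
    std::string s = as<std::string>(seqs[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      char c = s[p];
      if (c == 't') c = 'T';
      if (c >= 'a' && c <= 'z') c = c - 'a' + 'A';
      if (c == 'T') c = 'U';
      if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
        stop("non-ACGTU character '%s' in sequence %d", std::string(1, s[p]), (int)(i + 1));
      s[p] = c;
    }
    out[i] = foldEnergy(s);
  }
  return out;
}
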