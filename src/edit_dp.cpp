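#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Semi-global edit distance: the full peptide aligned against any region of
// the protein (free protein ends).  Residue-equivalence collapsing is done
// by the caller, which maps both strings through the equivalence classes
// before calling; here two residues match iff the mapped characters are
// equal.  Returns the minimum number of substitutions + insertions +
// deletions over all placements.
// [[Rcpp::export(name = ".semi_global_edit")]]
int semi_global_edit(std::string peptide, std::string protein) {
  const int m = (int)peptide.size();
  const int n = (int)protein.size();
  if (m == 0) return 0;
  if (n == 0) return m;
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  // row 0: aligning an empty peptide prefix costs 0 anywhere (free start)
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;  // peptide prefix against nothing: all insertions
    const char pc = peptide[(size_t)(i - 1)];
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (pc == protein[(size_t)(j - 1)] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return *std::min_element(prev.begin(), prev.end());
}

// Batch version: minimum over a set of proteins, with optional early-out
// threshold (stop scanning once a value <= stop_at is seen).
// [[Rcpp::export(name = ".semi_global_edit_min")]]
IntegerVector semi_global_edit_min(CharacterVector peptides,
                                   CharacterVector proteins,
                                   int stop_at) {
  const int np = peptides.size();
  IntegerVector out(np);
  std::vector<std::string> prots(proteins.size());
  for (int k = 0; k < proteins.size(); ++k)
    prots[(size_t)k] = as<std::string>(proteins[k]);
  for (int i = 0; i < np; ++i) {
    std::string pep = as<std::string>(peptides[i]);
    int best = (int)pep.size();
    for (size_t k = 0; k < prots.size(); ++k) {
      int d = semi_global_edit(pep, prots[k]);
      if (d < best) best = d;
      if (best <= stop_at) break;
    }
    out[i] = best;
  }
  return out;
}
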