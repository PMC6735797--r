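#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Minimum free energy of nested RNA secondary structure under a simplified
// nearest-neighbor model: only stacked adjacent base pairs contribute
// energy (negative stacking increments supplied by the caller as a 6x6
// pair-type matrix), hairpin loops must hold >= min_loop unpaired bases,
// and allowed pairs are Watson-Crick plus GU wobble.  The energy of a
// structure is the sum of stack(a,b) over pairs (i,j) whose inner neighbor
// (i+1,j-1) is also paired; the empty structure has energy 0, so the MFE is
// always <= 0.

static inline int pair_type(char a, char b) {
  // 0 AU, 1 UA, 2 CG, 3 GC, 4 GU, 5 UG, -1 not pairable
  if (a == 'A' && b == 'U') return 0;
  if (a == 'U' && b == 'A') return 1;
  if (a == 'C' && b == 'G') return 2;
  if (a == 'G' && b == 'C') return 3;
  if (a == 'G' && b == 'U') return 4;
  if (a == 'U' && b == 'G') return 5;
  return -1;
}

// [[Rcpp::export(name = ".fold_mfe_dp")]]
double fold_mfe_dp(std::string seq, NumericMatrix stack, int min_loop) {
  const int n = (int)seq.size();
  if (n < min_loop + 2) return 0.0;
  const double INF = 1e9;
  // V[i][j]: min energy of [i,j] given (i,j) paired; W[i][j]: unconstrained.
  std::vector<std::vector<double> > V((size_t)n, std::vector<double>((size_t)n, INF));
  std::vector<std::vector<double> > W((size_t)n, std::vector<double>((size_t)n, 0.0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pt = pair_type(seq[(size_t)i], seq[(size_t)j]);
      if (pt >= 0) {
        double best = W[(size_t)(i + 1)][(size_t)(j - 1)];
        int pt_in = (j - 1) - (i + 1) > min_loop
                        ? pair_type(seq[(size_t)(i + 1)], seq[(size_t)(j - 1)])
                        : -1;
        if (pt_in >= 0 && V[(size_t)(i + 1)][(size_t)(j - 1)] < INF / 2) {
          double stacked = V[(size_t)(i + 1)][(size_t)(j - 1)] + stack(pt, pt_in);
          if (stacked < best) best = stacked;
        }
        V[(size_t)i][(size_t)j] = best;
      }
      // W recurrence
      double w = W[(size_t)(i + 1)][(size_t)j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (pair_type(seq[(size_t)i], seq[(size_t)k]) >= 0 &&
            V[(size_t)i][(size_t)k] < INF / 2) {
          double cand = V[(size_t)i][(size_t)k] +
                        (k + 1 <= j ? W[(size_t)(k + 1)][(size_t)j] : 0.0);
          if (cand < w) w = cand;
        }
      }
      W[(size_t)i][(size_t)j] = std::min(w, 0.0);
    }
  }
  double res = W[0][(size_t)(n - 1)];
  return res < 0.0 ? res : 0.0;
}
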