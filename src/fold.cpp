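#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair weights: G:C -3, A:T -2, G:T -1; N unpairable.  Energy is
// stacking-aware: a pair contributes its weight only when its inward
// neighbor is also paired (helix continuation), and every helix pays a
// +4 initiation penalty, so lone pairs and short spurious helices are
// not rewarded.  Minimum hairpin loop of 3 unpaired bases.
static const double HELIX_INIT = 4.0;
static inline double pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1.0;
  return 1.0; // not pairable
}

// Nussinov-style minimum-energy nested folding with stacking-aware
// weights.  W(i,j): best energy on [i,j].  V(i,j): best energy on [i,j]
// given i:j paired; extending the helix inward adds the inner pair's
// weight.  Returns the minimum total energy (<= 0) over all nested
// structures.
// [[Rcpp::export(name = ".nussinov_mfe")]]
double nussinov_mfe(std::string seq) {
  int n = seq.size();
  if (n < 5) return 0.0;
  std::vector<double> W((size_t)n * n, 0.0), V((size_t)n * n, 0.0);
  auto wat = [&](int i, int j) -> double& { return W[(size_t)i * n + j]; };
  auto vat = [&](int i, int j) -> double& { return V[(size_t)i * n + j]; };
  for (int len = 5; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // V: i paired with j (feasibility checked by callers)
      double v = (i + 1 <= j - 1) ? wat(i + 1, j - 1) : 0.0;
      if (j - 1 - (i + 1) > 3) {
        double es = pair_energy(seq[i + 1], seq[j - 1]);
        if (es < 0) {
          double stacked = vat(i + 1, j - 1) + es;
          if (stacked < v) v = stacked;
        }
      }
      vat(i, j) = v;
      // W: i unpaired, or i paired with some k (outer pair itself free)
      double best = wat(i + 1, j);
      for (int k = i + 4; k <= j; ++k) {
        if (pair_energy(seq[i], seq[k]) > 0) continue;
        double right = (k + 1 <= j) ? wat(k + 1, j) : 0.0;
        double val = vat(i, k) + HELIX_INIT + right;
        if (val < best) best = val;
      }
      wat(i, j) = best;
    }
  }
  double mfe = wat(0, n - 1);
  return mfe > 0 ? 0.0 : mfe;
}
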