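#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Fallback folding engine: Nussinov-style dynamic program minimising a
// simple additive energy with fixed per-pair terms (GC -3, AU -2, GU -1
// kcal/mol) and a minimum hairpin loop of 3 nt. Not a thermodynamic model;
// used only when no Turner-parameter engine is on PATH.

static inline double pair_e(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0; // not pairable
}

// [[Rcpp::export]]
double pairmax_energy(std::string seq) {
  int n = seq.size();
  if (n == 0) stop("empty sequence");
  for (int i = 0; i < n; ++i) {
    char &c = seq[i];
    if (c == 'T') c = 'U';
  }
  if (n < 5) return 0.0;
  std::vector<double> E((size_t)n * n, 0.0);
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double best = E[(size_t)(i + 1) * n + j]; // i unpaired
      for (int k = i + 4; k <= j; ++k) {
        double pe = pair_e(seq[i], seq[k]);
        if (pe > 0) continue;
        double inner = (k - i >= 5) ? E[(size_t)(i + 1) * n + (k - 1)] : 0.0;
        double right = (k + 1 <= j) ? E[(size_t)(k + 1) * n + j] : 0.0;
        double cand = pe + inner + right;
        if (cand < best) best = cand;
      }
      E[(size_t)i * n + j] = best;
    }
  }
  double e = E[(size_t)0 * n + (n - 1)];
  return e < 0 ? e : 0.0;
}
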