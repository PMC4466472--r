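#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair-maximizing fold (Nussinov-style dynamic program) with a crude
// stacking-free energy assignment: GC -3, AU -2, GU -1 (kcal/mol per pair).
// Serves as a dependency-free fallback backend for hairpin evaluation; the
// default backend is a thermodynamic MFE engine.

static inline int pair_score(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

static void traceback(const std::vector<std::vector<int> > &M,
                      const std::string &s, int i, int j, int minloop,
                      std::string &db) {
  if (j - i < minloop + 1) return;
  int ps = pair_score(s[i], s[j]);
  if (ps > 0 && M[i][j] == M[i + 1][j - 1] + ps) {
    db[i] = '(';
    db[j] = ')';
    traceback(M, s, i + 1, j - 1, minloop, db);
    return;
  }
  if (M[i][j] == M[i + 1][j]) {
    traceback(M, s, i + 1, j, minloop, db);
    return;
  }
  if (M[i][j] == M[i][j - 1]) {
    traceback(M, s, i, j - 1, minloop, db);
    return;
  }
  for (int k = i + 1; k < j; ++k) {
    if (M[i][j] == M[i][k] + M[k + 1][j]) {
      traceback(M, s, i, k, minloop, db);
      traceback(M, s, k + 1, j, minloop, db);
      return;
    }
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int minloop = 3) {
  int n = seq.size();
  std::string db(n, '.');
  if (n < minloop + 2) {
    return List::create(_["structure"] = db, _["mfe"] = 0.0);
  }
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = minloop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = std::max(M[i + 1][j], M[i][j - 1]);
      int ps = pair_score(seq[i], seq[j]);
      if (ps > 0) best = std::max(best, M[i + 1][j - 1] + ps);
      for (int k = i + 1; k < j; ++k) {
        int v = M[i][k] + M[k + 1][j];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  traceback(M, seq, 0, n - 1, minloop, db);
  return List::create(_["structure"] = db, _["mfe"] = -(double)M[0][n - 1]);
}
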