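#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Scored base-pair maximisation (Nussinov-style) on DNA-canonicalised RNA.
// Pair scores: G:C = 3, A:T(U) = 2, G:T(U) wobble = 1. The reported
// "energy" is minus the total pair score, a stand-in free energy on the
// same side of zero as a thermodynamic MFE.

static inline int pairScore(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  if (n == 0) stop("empty sequence");
  // M[i][j]: best score on seq[i..j], 0-based inclusive
  std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        int s = pairScore(seq[k], seq[j]);
        if (s == 0) continue;
        int v = s + (k > i ? M[i][k - 1] : 0)
                  + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  // deterministic traceback: on ties prefer pairing j with the leftmost k
  std::string db(n, '.');
  std::stack< std::pair<int, int> > todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (j - i < min_loop + 1) continue;
    int target = M[i][j];
    int chosen = -1;
    for (int k = i; k <= j - min_loop - 1; ++k) {
      int s = pairScore(seq[k], seq[j]);
      if (s == 0) continue;
      int v = s + (k > i ? M[i][k - 1] : 0)
                + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
      if (v == target) { chosen = k; break; }
    }
    if (chosen < 0) {
      todo.push(std::make_pair(i, j - 1));
    } else {
      db[chosen] = '(';
      db[j] = ')';
      if (chosen > i) todo.push(std::make_pair(i, chosen - 1));
      if (chosen + 1 <= j - 1) todo.push(std::make_pair(chosen + 1, j - 1));
    }
  }

  int score = M[0][n - 1];
  return List::create(_["structure"] = db,
                      _["score"] = score,
                      _["energy"] = -score);
}
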