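#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// pair weights: GC = 3, AU = 2, GU = 1 (classic weighted base-pair
// maximization); 0 = cannot pair
static inline int pair_weight(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

// Weighted Nussinov base-pair maximization with a minimum hairpin loop
// size. Returns the dot-bracket structure, the number of pairs and the
// total pair weight; used as a fast non-thermodynamic folding backend.
// [[Rcpp::export]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) seq[i] = toupper(seq[i]);
  if (n == 0)
    return List::create(_["structure"] = "", _["pairs"] = 0,
                        _["weight"] = 0);
  std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = dp[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (w > 0) {
          int v = w + (k > i + 1 ? dp[i + 1][k - 1] : 0) +
                  (k < j ? dp[k + 1][j] : 0);
          if (v > best) best = v;
        }
      }
      dp[i][j] = best;
    }
  }
  // traceback (iterative, stack of segments)
  std::string db(n, '.');
  int pairs = 0;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (dp[i][j] == dp[i + 1][j]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      int w = pair_weight(seq[i], seq[k]);
      if (w == 0) continue;
      int v = w + (k > i + 1 ? dp[i + 1][k - 1] : 0) +
              (k < j ? dp[k + 1][j] : 0);
      if (v == dp[i][j]) {
        db[i] = '(';
        db[k] = ')';
        ++pairs;
        if (k > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return List::create(_["structure"] = db, _["pairs"] = pairs,
                      _["weight"] = dp[0][n - 1]);
}
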