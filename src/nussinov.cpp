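#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Base-pair maximisation (Watson-Crick + GU wobble, N never pairs) over
// nested structures with a minimum hairpin loop length, with deterministic
// traceback. Coordinates are 0-based internally; the returned partner
// vector is 1-based with 0 for unpaired.

static inline bool can_pair(char a, char b) {
  if (a == 'N' || b == 'N') return false;
  switch (a) {
    case 'A': return b == 'T' || b == 'U';
    case 'T': case 'U': return b == 'A' || b == 'G';
    case 'G': return b == 'C' || b == 'T' || b == 'U';
    case 'C': return b == 'G';
  }
  return false;
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) seq[i] = toupper(seq[i]);
  IntegerVector partner(n, 0);
  if (n == 0) return List::create(_["partner"] = partner,
                                  _["dot_bracket"] = std::string(""));
  // dp[i][j], j >= i-1 (dp over empty interval = 0)
  std::vector<std::vector<int>> dp(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = dp[i][j - 1]; // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!can_pair(seq[k], seq[j])) continue;
        int left = (k > i) ? dp[i][k - 1] : 0;
        int inner = (k + 1 <= j - 1) ? dp[k + 1][j - 1] : 0;
        int cand = left + 1 + inner;
        if (cand > best) best = cand;
      }
      dp[i][j] = best;
    }
  }
  // traceback: prefer pairing over leaving j unpaired, smallest k first
  std::stack<std::pair<int, int>> todo;
  todo.push({0, n - 1});
  while (!todo.empty()) {
    auto [i, j] = todo.top();
    todo.pop();
    if (i >= j || dp[i][j] == 0) continue;
    bool paired = false;
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!can_pair(seq[k], seq[j])) continue;
      int left = (k > i) ? dp[i][k - 1] : 0;
      int inner = (k + 1 <= j - 1) ? dp[k + 1][j - 1] : 0;
      if (left + 1 + inner == dp[i][j]) {
        partner[k] = j + 1;
        partner[j] = k + 1;
        if (k > i) todo.push({i, k - 1});
        if (k + 1 <= j - 1) todo.push({k + 1, j - 1});
        paired = true;
        break;
      }
    }
    if (!paired) todo.push({i, j - 1});
  }
  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i + 1) db[i] = '(';
    else if (partner[i] > 0) db[i] = ')';
  }
  return List::create(_["partner"] = partner, _["dot_bracket"] = db);
}
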