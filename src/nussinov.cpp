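#include <Rcpp.h>
#include <vector>
#include <string>
#include <utility>
using namespace Rcpp;

// Base-pair maximization (Nussinov-style) secondary-structure prediction with
// Watson-Crick + G.U wobble pairs, a minimum hairpin loop of `min_loop`
// unpaired bases, and a deterministic traceback: at every subproblem, leaving
// the 5' base unpaired is preferred when it attains the optimum; otherwise the
// smallest admissible partner index is taken.

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export]]
IntegerMatrix nussinov_cpp(const std::string& seq, int min_loop) {
  const int n = seq.size();
  std::vector<int> N(n * n, 0);
  auto idx = [n](int i, int j) { return i * n + j; };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = N[idx(i + 1, j)];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int inner = (k - i > 1) ? N[idx(i + 1, k - 1)] : 0;
        int outer = (k < j) ? N[idx(k + 1, j)] : 0;
        int cand = 1 + inner + outer;
        if (cand > best) best = cand;
      }
      N[idx(i, j)] = best;
    }
  }

  std::vector<std::pair<int, int> > pairs;
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= min_loop) continue;
    if (N[idx(i, j)] == N[idx(i + 1, j)]) {  // prefer i unpaired
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {  // then smallest partner
      if (!can_pair(seq[i], seq[k])) continue;
      int inner = (k - i > 1) ? N[idx(i + 1, k - 1)] : 0;
      int outer = (k < j) ? N[idx(k + 1, j)] : 0;
      if (1 + inner + outer == N[idx(i, j)]) {
        pairs.push_back(std::make_pair(i + 1, k + 1));  // 1-based
        if (k - i > 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }

  IntegerMatrix out(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}
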