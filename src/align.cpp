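#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gap penalty: a gap
// run of length L costs gap_open + gap_ext * L.  The run-opening cost makes a
// contiguous indel strictly better than any equal-length split, so planted
// indels are recovered as single events.  The traceback is deterministic:
// states and predecessors are preferred in the order M (aligned) > X (gap in
// the reference, consuming a query base) > Y (gap in the query).
//
// [[Rcpp::export]]
List nw_align_cpp(const std::string& query, const std::string& ref,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int n = query.size();
  const int m = ref.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  auto at = [W](int i, int j) { return i * W + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = gap_open + gap_ext * i;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = gap_open + gap_ext * j;

  for (int i = 1; i <= n; ++i) {
    const char qi = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double s = (qi == ref[j - 1]) ? match : mismatch;
      double best = M[at(i - 1, j - 1)];
      if (X[at(i - 1, j - 1)] > best) best = X[at(i - 1, j - 1)];
      if (Y[at(i - 1, j - 1)] > best) best = Y[at(i - 1, j - 1)];
      M[at(i, j)] = best + s;

      double xo = M[at(i - 1, j)] + gap_open + gap_ext;
      double yo2 = Y[at(i - 1, j)] + gap_open + gap_ext;  // switch gap side
      double xe = X[at(i - 1, j)] + gap_ext;
      double xbest = xo;
      if (xe > xbest) xbest = xe;
      if (yo2 > xbest) xbest = yo2;
      X[at(i, j)] = xbest;

      double yo = M[at(i, j - 1)] + gap_open + gap_ext;
      double xo2 = X[at(i, j - 1)] + gap_open + gap_ext;
      double ye = Y[at(i, j - 1)] + gap_ext;
      double ybest = yo;
      if (ye > ybest) ybest = ye;
      if (xo2 > ybest) ybest = xo2;
      Y[at(i, j)] = ybest;
    }
  }

  // final state: prefer M > X > Y among optima
  double score = M[at(n, m)];
  int state = 0;
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  std::string aq, ar;
  aq.reserve(n + m);
  ar.reserve(n + m);
  int i = n, j = m;
  const double eps = 1e-9;
  auto eq = [eps](double a, double b) {
    return a == b || std::fabs(a - b) <= eps;
  };
  while (i > 0 || j > 0) {
    if (state == 0) {
      const double s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      const double target = M[at(i, j)] - s;
      aq.push_back(query[i - 1]);
      ar.push_back(ref[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (eq(M[at(i, j)], target)) state = 0;
      else if (eq(X[at(i, j)], target)) state = 1;
      else state = 2;
    } else if (state == 1) {
      aq.push_back(query[i - 1]);
      ar.push_back('-');
      --i;
      if (i == 0 && j == 0) break;
      if (eq(M[at(i, j)] + gap_open + gap_ext, X[at(i + 1, j)])) state = 0;
      else if (eq(X[at(i, j)] + gap_ext, X[at(i + 1, j)])) state = 1;
      else state = 2;
    } else {
      aq.push_back('-');
      ar.push_back(ref[j - 1]);
      --j;
      if (i == 0 && j == 0) break;
      if (eq(M[at(i, j)] + gap_open + gap_ext, Y[at(i, j + 1)])) state = 0;
      else if (eq(Y[at(i, j)] + gap_ext, Y[at(i, j + 1)])) state = 2;
      else state = 1;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());

  return List::create(_["aligned_query"] = aq,
                      _["aligned_ref"] = ar,
                      _["score"] = score);
}
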