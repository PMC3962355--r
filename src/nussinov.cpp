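#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted Nussinov maximum-pairing fold.
// Pair weights: G:C = 3, A:U = 2, G:U = 1 (T treated as U).
// Minimum hairpin loop of 3 unpaired bases; no pseudoknots.
// Positions flagged in `forbidden` are constrained to stay unpaired
// (used for target-site opening-cost calculations).
// Traceback is deterministic: on ties a pairing is preferred over leaving
// the 3' base unpaired, and the 5'-most partner is chosen.

static inline int pair_weight(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
List nussinov_fold_cpp(std::string seq, LogicalVector forbidden) {
  const int n = seq.size();
  if ((int)forbidden.size() != n)
    stop("constraint mask length must equal sequence length");
  const int minloop = 3;

  std::vector<int> w(n, 0);  // usable flag per position
  for (int i = 0; i < n; ++i) w[i] = forbidden[i] ? 0 : 1;

  // M[i][j] stored as flat vector, j >= i
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = minloop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i][j - 1];  // j unpaired
      if (w[j]) {
        for (int k = i; k <= j - minloop - 1; ++k) {
          if (!w[k]) continue;
          int pw = pair_weight(seq[k], seq[j]);
          if (pw == 0) continue;
          int cand = pw + (k > i ? M[i][k - 1] : 0) + M[k + 1][j - 1];
          if (cand > best) best = cand;
        }
      }
      M[i][j] = best;
    }
  }

  // traceback
  IntegerVector partner(n, 0);  // 1-based partner, 0 = unpaired
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < minloop + 1) continue;
    int best = M[i][j];
    int chosen = -1;
    if (w[j]) {
      for (int k = i; k <= j - minloop - 1; ++k) {
        if (!w[k]) continue;
        int pw = pair_weight(seq[k], seq[j]);
        if (pw == 0) continue;
        int cand = pw + (k > i ? M[i][k - 1] : 0) + M[k + 1][j - 1];
        if (cand == best) { chosen = k; break; }  // 5'-most partner
      }
    }
    if (chosen >= 0) {
      partner[chosen] = j + 1;
      partner[j] = chosen + 1;
      if (chosen > i) stack.push_back(std::make_pair(i, chosen - 1));
      stack.push_back(std::make_pair(chosen + 1, j - 1));
    } else {
      stack.push_back(std::make_pair(i, j - 1));
    }
  }

  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i + 1) db[i] = '(';
    else if (partner[i] > 0) db[i] = ')';
  }

  return List::create(
    _["structure"] = db,
    _["score"] = n > 0 ? M[0][n - 1] : 0,
    _["partner"] = partner);
}
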