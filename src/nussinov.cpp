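#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Parse a dot-bracket string into a 1-based pair table (-1 = unpaired).
// [[Rcpp::export(name = ".db_pairtable_cpp")]]
IntegerVector db_pairtable_cpp(std::string db) {
  const int n = (int) db.size();
  IntegerVector pt(n, -1);
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (db[i] == '(') stack.push_back(i);
    else if (db[i] == ')') {
      if (stack.empty()) stop("unbalanced dot-bracket string");
      int j = stack.back(); stack.pop_back();
      pt[i] = j + 1; pt[j] = i + 1;
    } else if (db[i] != '.') stop("invalid dot-bracket character");
  }
  if (!stack.empty()) stop("unbalanced dot-bracket string");
  return pt;
}

// Allowed pairs: AU, UA, GC, CG, GU, UG (wobble included).
static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'U';
  case 'U': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'U';
  case 'C': return b == 'G';
  default:  return false;
  }
}

// Base-pair maximisation (Nussinov) with a minimum hairpin loop size.
// Recurrence over M[i][j] = max pairs in seq[i..j]:
//   M[i][j] = max( M[i+1][j],
//                  max_{k: pairable(i,k), k-i>min_loop} M[i+1][k-1] + M[k+1][j] + 1 )
// Traceback deterministically prefers leaving i unpaired, then pairing i
// with the smallest feasible k.
// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  std::vector<int> pt(n, -1);
  if (n == 0)
    return List::create(_["pair_table"] = IntegerVector(0), _["pair_count"] = 0);

  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int v = 1 + (k > i + 1 ? M[i + 1][k - 1] : 0) + (k < j ? M[k + 1][j] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  // iterative traceback
  std::vector<std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= min_loop) continue;
    if (M[i][j] == M[i + 1][j]) {        // i unpaired first
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int v = 1 + (k > i + 1 ? M[i + 1][k - 1] : 0) + (k < j ? M[k + 1][j] : 0);
      if (v == M[i][j]) {                // smallest feasible partner
        pt[i] = k; pt[k] = i;
        if (k > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j)     stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }

  IntegerVector pair_table(n);
  int pc = 0;
  for (int i = 0; i < n; ++i) {
    pair_table[i] = pt[i] < 0 ? -1 : pt[i] + 1;  // 1-based for R, -1 unpaired
    if (pt[i] > i) ++pc;
  }
  return List::create(_["pair_table"] = pair_table, _["pair_count"] = pc);
}
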