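#include <Rcpp.h>
#include <string>
#include <vector>
#include <stack>
using namespace Rcpp;

// Base-pair maximization (Nussinov) over {AU/AT, GC, GU/GT} with a minimum
// hairpin loop. Recurrence: best(i,j) = max( best(i+1,j),
//   max_k { pair(i,k) : best(i+1,k-1) + best(k+1,j) + 1 } ).
// Traceback ties are broken toward pairing the 5'-most position with its
// 5'-most admissible partner, which makes the reported structure (not just
// the pair count) deterministic.

static inline bool can_pair(char a, char b) {
  if (a == 'U') a = 'T';
  if (b == 'U') b = 'T';
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, int min_loop) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) seq[i] = toupper(seq[i]);
  if (n == 0) return List::create(_["pairs"] = 0, _["structure"] = "");
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
        int outer = (k + 1 <= j) ? M[k + 1][j] : 0;
        int cand = inner + outer + 1;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }
  // traceback
  std::string db(n, '.');
  std::stack<std::pair<int, int> > st;
  st.push(std::make_pair(0, n - 1));
  while (!st.empty()) {
    std::pair<int, int> iv = st.top();
    st.pop();
    int i = iv.first, j = iv.second;
    if (i >= j || j - i < min_loop + 1) continue;
    int best = M[i][j];
    if (best == 0) continue;
    bool placed = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
      int outer = (k + 1 <= j) ? M[k + 1][j] : 0;
      if (inner + outer + 1 == best) {
        db[i] = '(';
        db[k] = ')';
        if (k - 1 > i + 1) st.push(std::make_pair(i + 1, k - 1));
        if (k + 1 < j) st.push(std::make_pair(k + 1, j));
        placed = true;
        break;
      }
    }
    if (!placed) st.push(std::make_pair(i + 1, j));
  }
  int pairs = M[0][n - 1];
  return List::create(_["pairs"] = pairs, _["structure"] = db);
}
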