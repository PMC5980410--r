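#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-neighbour offsets enumerated in ascending linear-index order for a
// column-major matrix: (dr, dc) sorted by dc then dr. Deterministic
// tie-breaking everywhere relies on this order.
static const int DR[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DC[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

// Label 8-connected components of a logical mask. Components are numbered in
// the order their first cell (smallest column-major linear index) is reached.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(r + c * nr);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = cr + DR[k], c2 = cc + DC[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Steepest-ascent watershed assignment. Every masked cell follows the path of
// steepest ascent (8-neighbourhood restricted to the mask; among equally high
// strictly-greater neighbours the one with the smallest linear index wins)
// until it reaches a summit. Summits carrying a marker id take that label and
// pass it down their catchment. Plateaus (no strictly greater neighbour but
// equal-valued neighbours) are resolved by breadth-first propagation from
// already-resolved equal-valued cells in ascending-index order, which is the
// geodesic-nearest-ascending-exit rule. Summits without a marker id keep
// label 0; their terminal cell index (1-based) is reported so the caller can
// merge them.
// [[Rcpp::export]]
List cpp_steepest_labels(NumericMatrix v, LogicalMatrix mask,
                         IntegerMatrix markers) {
  int nr = v.nrow(), nc = v.ncol(), n = nr * nc;
  std::vector<int> ptr(n, -2); // -2 outside mask, -1 pending plateau, else idx
  std::vector<char> isSelf(n, 0);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = r + c * nr;
      if (!mask(r, c)) continue;
      double own = v(r, c);
      double best = R_NegInf;
      int bestIdx = -1;
      bool hasEqual = false;
      for (int k = 0; k < 8; ++k) {
        int r2 = r + DR[k], c2 = c + DC[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (!mask(r2, c2)) continue;
        double nv = v(r2, c2);
        if (nv > best) { best = nv; bestIdx = r2 + c2 * nr; }
        if (nv == own) hasEqual = true;
      }
      if (bestIdx >= 0 && best > own) {
        ptr[idx] = bestIdx;
      } else if (markers[idx] > 0) {
        ptr[idx] = idx; isSelf[idx] = 1;
      } else if (hasEqual) {
        ptr[idx] = -1; // plateau, resolved below
      } else {
        ptr[idx] = idx; isSelf[idx] = 1; // unmarked strict summit
      }
    }
  }

  // plateau resolution: FIFO from resolved cells, ascending index seeds
  std::queue<int> q;
  for (int i = 0; i < n; ++i) if (ptr[i] >= 0) q.push(i);
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 8; ++k) {
      int r2 = r + DR[k], c2 = c + DC[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int j = r2 + c2 * nr;
      if (ptr[j] == -1 && v(r2, c2) == v(idx % nr, idx / nr)) {
        ptr[j] = idx;
        q.push(j);
      }
    }
  }
  // isolated plateau components never reached (all-equal, no marker): self
  for (int i = 0; i < n; ++i) {
    if (ptr[i] == -1) { ptr[i] = i; isSelf[i] = 1; }
  }

  // path compression to terminal, then label lookup
  IntegerMatrix lab(nr, nc);
  IntegerVector term(n, 0);
  std::vector<int> stack;
  std::vector<int> terminal(n, -1);
  for (int i = 0; i < n; ++i) {
    if (ptr[i] == -2 || terminal[i] >= 0) continue;
    stack.clear();
    int j = i;
    while (terminal[j] < 0 && !isSelf[j]) {
      stack.push_back(j);
      j = ptr[j];
    }
    int t = isSelf[j] ? j : terminal[j];
    terminal[j] = t;
    for (size_t s = 0; s < stack.size(); ++s) terminal[stack[s]] = t;
  }
  for (int i = 0; i < n; ++i) {
    if (ptr[i] == -2) continue;
    int t = terminal[i];
    lab[i] = markers[t];
    term[i] = t + 1;
  }
  return List::create(_["labels"] = lab, _["terminal"] = term);
}
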