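#include <Rcpp.h>
#include <chrono>
#include <vector>
using namespace Rcpp;

// Maximum common connected induced subgraph between two molecular graphs.
//
// Atom compatibility: equal element code. Bond compatibility: equal bond
// order, with aromatic bonds carrying their own order code so aromatic
// systems only match aromatic systems. The search is a branch-and-bound
// extension of a partial atom mapping along the common-subgraph frontier;
// root pairs are canonicalized (the lowest mapped atom of A anchors the
// mapping) so each common subgraph is explored once.

struct McsSearch {
  int nA, nB;
  const std::vector<int>& elemA;
  const std::vector<int>& elemB;
  std::vector<std::vector<int>> ordA, ordB; // 0 = no bond
  int best;
  bool timed_out;
  std::chrono::steady_clock::time_point deadline;
  std::vector<int> mapA; // A index -> B index or -1
  std::vector<int> mapB;
  std::vector<int> order; // mapped A atoms in insertion order
  int root;

  McsSearch(const std::vector<int>& eA, const std::vector<int>& eB)
      : nA(eA.size()), nB(eB.size()), elemA(eA), elemB(eB),
        best(0), timed_out(false) {}

  bool consistent(int a, int b) {
    if (elemA[a] != elemB[b]) return false;
    for (int x : order) {
      int oa = ordA[a][x];
      int ob = ordB[b][mapA[x]];
      if (oa != ob) return false; // induced: bond present iff present, same order
    }
    return true;
  }

  void extend() {
    if (timed_out) return;
    if (std::chrono::steady_clock::now() > deadline) { timed_out = true; return; }
    int size = order.size();
    if (size > best) best = size;
    // admissible bound: every future atom comes from the unmapped A atoms
    // with index above the root (and needs an unmapped B partner)
    int remA = 0;
    for (int a = root + 1; a < nA; ++a) remA += (mapA[a] < 0);
    if (size + std::min(remA, nB - size) <= best) return;
    // frontier: unmapped A atoms adjacent to the mapped set, index > root
    std::vector<char> cand(nA, 0);
    for (int x : order)
      for (int a = root + 1; a < nA; ++a)
        if (mapA[a] < 0 && ordA[x][a] > 0) cand[a] = 1;
    for (int a = 0; a < nA && !timed_out; ++a) {
      if (!cand[a]) continue;
      for (int b = 0; b < nB && !timed_out; ++b) {
        if (mapB[b] >= 0) continue;
        if (!consistent(a, b)) continue;
        mapA[a] = b; mapB[b] = a; order.push_back(a);
        extend();
        order.pop_back(); mapA[a] = -1; mapB[b] = -1;
      }
      // pruning: if skipping atom a entirely cannot beat best, still need
      // to consider subgraphs omitting a, so no break here
    }
  }

  List run(const IntegerMatrix& bondsA, const IntegerMatrix& bondsB,
           double budget_ms) {
    ordA.assign(nA, std::vector<int>(nA, 0));
    ordB.assign(nB, std::vector<int>(nB, 0));
    for (int k = 0; k < bondsA.nrow(); ++k) {
      int i = bondsA(k, 0) - 1, j = bondsA(k, 1) - 1, o = bondsA(k, 2);
      ordA[i][j] = o; ordA[j][i] = o;
    }
    for (int k = 0; k < bondsB.nrow(); ++k) {
      int i = bondsB(k, 0) - 1, j = bondsB(k, 1) - 1, o = bondsB(k, 2);
      ordB[i][j] = o; ordB[j][i] = o;
    }
    deadline = std::chrono::steady_clock::now() +
               std::chrono::milliseconds((long long)budget_ms);
    mapA.assign(nA, -1);
    mapB.assign(nB, -1);
    for (int a = 0; a < nA && !timed_out; ++a) {
      if (nA - a <= best) break; // roots left cannot beat best
      for (int b = 0; b < nB && !timed_out; ++b) {
        if (elemA[a] != elemB[b]) continue;
        root = a;
        mapA[a] = b; mapB[b] = a; order.push_back(a);
        extend();
        order.pop_back(); mapA[a] = -1; mapB[b] = -1;
      }
    }
    return List::create(Named("size") = best,
                        Named("timed_out") = timed_out);
  }
};

// [[Rcpp::export]]
List mcs_size_cpp(IntegerVector elem_a, IntegerMatrix bonds_a,
                  IntegerVector elem_b, IntegerMatrix bonds_b,
                  double budget_ms) {
  std::vector<int> eA(elem_a.begin(), elem_a.end());
  std::vector<int> eB(elem_b.begin(), elem_b.end());
  if (eA.empty() || eB.empty())
    return List::create(Named("size") = 0, Named("timed_out") = false);
  McsSearch s(eA, eB);
  return s.run(bonds_a, bonds_b, budget_ms);
}
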