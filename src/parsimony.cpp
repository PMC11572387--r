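#include <Rcpp.h>
using namespace Rcpp;

// Unit-cost (unordered / Fitch-type) parsimony on rooted trees with
// arbitrary multifurcations, via Sankoff dynamic programming. Tip
// observations are bitmask state sets (bit j = state j allowed), so missing
// data and polymorphisms cost nothing to realize. The up-pass yields exact
// MPR (most-parsimonious-reconstruction) state sets per node.
//
// Node indexing: 0..nTip-1 are tips (rows of tipMasks), nTip..nNodes-1 are
// internal nodes. `internalPost` lists internal nodes in postorder
// (children before parents); `childVec`/`childOff` give each internal
// node's children in CSR layout, aligned with `internalPost`.

static const int INF = 1000000;

// [[Rcpp::export]]
List sankoff_unit_cpp(IntegerMatrix tipMasks,
                      IntegerVector nStates,
                      IntegerVector internalPost,
                      IntegerVector childVec,
                      IntegerVector childOff,
                      bool wantSets) {
  const int nTip = tipMasks.nrow();
  const int nChar = tipMasks.ncol();
  const int nInt = internalPost.size();
  const int nNodes = nTip + nInt;
  const int root = internalPost[nInt - 1];

  IntegerVector steps(nChar);
  IntegerMatrix mpr;  // bitmask per (node, char)
  if (wantSets) mpr = IntegerMatrix(nNodes, nChar);

  std::vector<int> down(nNodes * 16);
  std::vector<int> up;
  if (wantSets) up.resize(nNodes * 16);

  for (int c = 0; c < nChar; c++) {
    const int ns = nStates[c];
    // tips
    for (int t = 0; t < nTip; t++) {
      const int mask = tipMasks(t, c);
      for (int s = 0; s < ns; s++)
        down[t * 16 + s] = (mask >> s) & 1 ? 0 : INF;
    }
    // postorder down-pass
    for (int i = 0; i < nInt; i++) {
      const int v = internalPost[i];
      int *dv = &down[v * 16];
      for (int s = 0; s < ns; s++) dv[s] = 0;
      for (int k = childOff[i]; k < childOff[i + 1]; k++) {
        const int w = childVec[k];
        const int *dw = &down[w * 16];
        int mn = INF;
        for (int s = 0; s < ns; s++) if (dw[s] < mn) mn = dw[s];
        for (int s = 0; s < ns; s++) {
          int add = dw[s] < mn + 1 ? dw[s] : mn + 1;
          dv[s] += add;
        }
      }
    }
    int L = INF;
    const int *dr = &down[root * 16];
    for (int s = 0; s < ns; s++) if (dr[s] < L) L = dr[s];
    steps[c] = L;

    if (!wantSets) continue;

    // up-pass: up[v][s] = best cost of the rest of the tree given node v
    // is in state s. For the root this is 0.
    for (int s = 0; s < ns; s++) up[root * 16 + s] = 0;
    for (int i = nInt - 1; i >= 0; i--) {
      const int u = internalPost[i];
      const int *uu = &up[u * 16];
      const int from = childOff[i], to = childOff[i + 1];
      for (int k = from; k < to; k++) {
        const int v = childVec[k];
        // A(s) = up_u(s) + sum over siblings w of min(down_w(s), 1+min down_w)
        int A[16];
        for (int s = 0; s < ns; s++) A[s] = uu[s];
        for (int k2 = from; k2 < to; k2++) {
          if (k2 == k) continue;
          const int w = childVec[k2];
          const int *dw = &down[w * 16];
          int mn = INF;
          for (int s = 0; s < ns; s++) if (dw[s] < mn) mn = dw[s];
          for (int s = 0; s < ns; s++) {
            int add = dw[s] < mn + 1 ? dw[s] : mn + 1;
            A[s] += add;
          }
        }
        int mnA = INF;
        for (int s = 0; s < ns; s++) if (A[s] < mnA) mnA = A[s];
        int *uv = &up[v * 16];
        for (int s = 0; s < ns; s++)
          uv[s] = A[s] < mnA + 1 ? A[s] : mnA + 1;
      }
    }
    for (int v = 0; v < nNodes; v++) {
      const int *dv = &down[v * 16];
      const int *uv = &up[v * 16];
      int mask = 0;
      for (int s = 0; s < ns; s++)
        if (dv[s] + uv[s] == L) mask |= (1 << s);
      mpr(v, c) = mask;
    }
  }

  if (wantSets) return List::create(_["steps"] = steps, _["mpr"] = mpr);
  return List::create(_["steps"] = steps);
}

// ---- fast path for heuristic search ---------------------------------------
// Trees inside the search are parent vectors: nodes 1..nNodes, tips
// 1..nTip (fixed ids matching tipMasks rows), parent[root-1] == 0.

#include "ptree.h"

static void ptree_csr(IntegerVector parent, int nTip,
                      std::vector<int> &internalPost,
                      std::vector<int> &childVec,
                      std::vector<int> &childOff) {
  ptree_csr_build(parent, nTip, internalPost, childVec, childOff);
}

// [[Rcpp::export]]
IntegerVector ptree_steps_cpp(IntegerVector parent, int nTip,
                              IntegerMatrix tipMasks, IntegerVector nStates) {
  std::vector<int> ip, cv, co;
  ptree_csr(parent, nTip, ip, cv, co);
  List res = sankoff_unit_cpp(tipMasks, nStates,
                              IntegerVector(ip.begin(), ip.end()),
                              IntegerVector(cv.begin(), cv.end()),
                              IntegerVector(co.begin(), co.end()), false);
  return res["steps"];
}

// Search objective, to be minimized. Equal weights: weighted tree length.
// Implied weights: sum_i w_i * h_i / (h_i + k) with h_i = s_i - m_i
// (minimizing this maximizes the Goloboff fit sum_i w_i * k/(k+h_i)).
// [[Rcpp::export]]
double ptree_objective_cpp(IntegerVector parent, int nTip,
                           IntegerMatrix tipMasks, IntegerVector nStates,
                           NumericVector weights, IntegerVector minSteps,
                           bool implied, double k) {
  IntegerVector steps = ptree_steps_cpp(parent, nTip, tipMasks, nStates);
  double obj = 0.0;
  for (int c = 0; c < steps.size(); c++) {
    if (implied) {
      double h = steps[c] - minSteps[c];
      obj += weights[c] * h / (h + k);
    } else {
      obj += weights[c] * steps[c];
    }
  }
  return obj;
}

// Weighted total length (used by bootstrap and implied-weights search where
// characters carry integer resampling weights).
// [[Rcpp::export]]
double tree_length_weighted_cpp(IntegerMatrix tipMasks,
                                IntegerVector nStates,
                                IntegerVector internalPost,
                                IntegerVector childVec,
                                IntegerVector childOff,
                                NumericVector weights) {
  List res = sankoff_unit_cpp(tipMasks, nStates, internalPost, childVec,
                              childOff, false);
  IntegerVector steps = res["steps"];
  double tot = 0.0;
  for (int c = 0; c < steps.size(); c++) tot += weights[c] * steps[c];
  return tot;
}
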