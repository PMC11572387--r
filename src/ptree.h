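#ifndef PALEOTIP_PTREE_H
#define PALEOTIP_PTREE_H

#include <Rcpp.h>
#include <vector>

// Parent-vector trees: nodes 1..nNodes, tips 1..nTip, parent[root-1] == 0.
// Builds internal nodes in postorder plus a CSR children table (0-based).
inline void ptree_csr_build(Rcpp::IntegerVector parent, int nTip,
                            std::vector<int> &internalPost,
                            std::vector<int> &childVec,
                            std::vector<int> &childOff) {
  const int nNodes = parent.size();
  std::vector<std::vector<int> > kids(nNodes);
  int root = -1;
  for (int v = 0; v < nNodes; v++) {
    if (parent[v] == 0) root = v;
    else kids[parent[v] - 1].push_back(v);
  }
  std::vector<int> stack, order;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    for (size_t j = 0; j < kids[v].size(); j++)
      if (kids[v][j] >= nTip) stack.push_back(kids[v][j]);
  }
  internalPost.assign(order.rbegin(), order.rend());
  childOff.resize(internalPost.size() + 1);
  childOff[0] = 0;
  childVec.clear();
  for (size_t i = 0; i < internalPost.size(); i++) {
    const std::vector<int> &k = kids[internalPost[i]];
    childVec.insert(childVec.end(), k.begin(), k.end());
    childOff[i + 1] = childVec.size();
  }
}

#endif
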