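#include <Rcpp.h>
using namespace Rcpp;

// Exact interventional subset expectations for a tree ensemble.
//
// For every evaluation row x and every feature subset S (bitmask over the
// M features), computes
//   v(S) = mean over background rows b of f(x_S, b_{~S}),
// averaged over trees. Shapley values and pairwise Shapley interaction
// values are exact weighted sums over this table; with M <= ~12 the 2^M
// enumeration is feasible and transparently correct. Interventional
// conditioning makes the decomposition the functional ANOVA of the fitted
// ensemble: a feature absent from the fitted function gets exactly zero
// attribution, and a purely additive fit has exactly zero pairwise terms.
//
// Per tree, each leaf is reached by (x_S, b_{~S}) iff x satisfies every
// split on the path for features in S and b satisfies every split for
// path features outside S. Backgrounds are pushed through each tree once,
// tallying for every leaf how many backgrounds satisfy each subset of its
// path-feature constraints (a superset-sum over path submasks); each
// evaluation row then needs only one walk plus a 2^M combination pass.
//
// Trees arrive flattened: integer children (-1 = leaf), 0-based split
// variable, split value, leaf predictions. Split rule: x <= value goes
// left (ranger's convention for numeric splits).

struct TreeArrays {
  IntegerVector left, right, var;
  NumericVector val, pred;
};

// walk one row through every path of the tree, recording per leaf the
// bitmask of path features whose splits the row satisfies everywhere
static void walkRow(const TreeArrays& tr, int node, const double* row,
                    unsigned int viol, unsigned int dmask,
                    std::vector<unsigned int>& leafD,
                    std::vector<unsigned int>& leafSat,
                    std::vector<int>& leafId,
                    int& leafCount) {
  if (tr.left[node] < 0) {
    leafD[leafCount] = dmask;
    leafSat[leafCount] = dmask & ~viol;
    leafId[leafCount] = node;
    ++leafCount;
    return;
  }
  int f = tr.var[node];
  unsigned int bit = 1u << f;
  bool goesLeft = row[f] <= tr.val[node];
  walkRow(tr, tr.left[node], row, goesLeft ? viol : (viol | bit),
          dmask | bit, leafD, leafSat, leafId, leafCount);
  walkRow(tr, tr.right[node], row, goesLeft ? (viol | bit) : viol,
          dmask | bit, leafD, leafSat, leafId, leafCount);
}

// [[Rcpp::export(name = ".treeSubsetValues")]]
NumericMatrix treeSubsetValues(List trees, NumericMatrix X,
                               NumericMatrix B) {
  const int M = X.ncol();
  if (B.ncol() != M) stop("background and evaluation columns differ");
  if (M > 14) stop("subset enumeration supports at most 14 features");
  const int nMask = 1 << M;
  const int n = X.nrow();
  const int nB = B.nrow();
  const int T = trees.size();

  NumericMatrix V(n, nMask);
  std::vector<double> v(nMask);

  // row-major copies for cheap row access
  std::vector<double> Xr(n * M), Br(nB * M);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < M; ++j) Xr[i * M + j] = X(i, j);
  for (int i = 0; i < nB; ++i)
    for (int j = 0; j < M; ++j) Br[i * M + j] = B(i, j);

  std::vector<unsigned int> leafD, leafSat;
  std::vector<int> leafId;
  std::vector<double> Vall(n * nMask, 0.0);

  for (int t = 0; t < T; ++t) {
    List tt = trees[t];
    TreeArrays tr;
    tr.left = as<IntegerVector>(tt["left"]);
    tr.right = as<IntegerVector>(tt["right"]);
    tr.var = as<IntegerVector>(tt["var"]);
    tr.val = as<NumericVector>(tt["val"]);
    tr.pred = as<NumericVector>(tt["pred"]);
    const int nn = tr.left.size();
    int nLeaf = 0;
    for (int k = 0; k < nn; ++k) if (tr.left[k] < 0) ++nLeaf;
    leafD.assign(nLeaf, 0u);
    leafSat.assign(nLeaf, 0u);
    leafId.assign(nLeaf, 0);

    // background tallies: cnt[L][s] = #b whose values satisfy every
    // path constraint of leaf L on each feature in s (after zeta pass)
    std::vector<double> cnt((size_t)nLeaf * nMask, 0.0);
    for (int b = 0; b < nB; ++b) {
      int lc = 0;
      walkRow(tr, 0, &Br[(size_t)b * M], 0u, 0u, leafD, leafSat, leafId,
              lc);
      for (int L = 0; L < lc; ++L) cnt[(size_t)L * nMask + leafSat[L]] += 1;
    }
    // superset-sum restricted to each leaf's path mask
    for (int L = 0; L < nLeaf; ++L) {
      unsigned int D = leafD[L];
      double* c = &cnt[(size_t)L * nMask];
      for (int f = 0; f < M; ++f) {
        unsigned int bit = 1u << f;
        if (!(D & bit)) continue;
        for (unsigned int m = 0; m < (unsigned int)nMask; ++m) {
          if ((m & D) == m && !(m & bit)) c[m] += c[m | bit];
        }
      }
    }

    for (int i = 0; i < n; ++i) {
      int lc = 0;
      walkRow(tr, 0, &Xr[(size_t)i * M], 0u, 0u, leafD, leafSat, leafId,
              lc);
      double* vi = &Vall[(size_t)i * nMask];
      for (int L = 0; L < lc; ++L) {
        unsigned int D = leafD[L];
        unsigned int okx = leafSat[L];         // x-satisfied path features
        double leafVal = tr.pred[leafId[L]] / nB;
        const double* c = &cnt[(size_t)L * nMask];
        for (unsigned int m = 0; m < (unsigned int)nMask; ++m) {
          // need every in-subset path feature satisfied by x ...
          if ((m & D & ~okx) != 0u) continue;
          // ... and count backgrounds satisfying the rest of the path
          double nb = c[D & ~m];
          if (nb > 0) vi[m] += leafVal * nb;
        }
      }
      if (i % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < nMask; ++m) V(i, m) = Vall[(size_t)i * nMask + m] / T;
  return V;
}
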