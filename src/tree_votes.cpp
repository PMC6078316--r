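#include <Rcpp.h>
using namespace Rcpp;

// Per-tree class votes for a fitted classification forest, computed by
// traversing the stored tree arrays directly.
//
// Encoding of a ranger classification forest (numeric predictors only):
//  - childLeft[[t]], childRight[[t]]: 0-based child node ids; both 0 marks a
//    terminal node (the root is node 0 and is terminal iff both are 0);
//  - splitVar[[t]]: 0-based predictor column index of the split;
//  - splitVal[[t]]: split threshold for internal nodes ("<=" goes left);
//    for terminal nodes the slot holds the predicted class as a 1-based
//    factor level code.
//
// Returns an n x ntree integer matrix of 1-based class codes.
// [[Rcpp::export]]
IntegerMatrix tree_votes_cpp(NumericMatrix x,
                             List childLeft, List childRight,
                             List splitVar, List splitVal) {
  const int n = x.nrow();
  const int ntree = childLeft.size();
  IntegerMatrix votes(n, ntree);

  for (int t = 0; t < ntree; ++t) {
    IntegerVector left = childLeft[t];
    IntegerVector right = childRight[t];
    IntegerVector var = splitVar[t];
    NumericVector val = splitVal[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (left[node] != 0 || right[node] != 0) {
        node = (x(i, var[node]) <= val[node]) ? left[node] : right[node];
      }
      votes(i, t) = (int) val[node];
    }
  }
  return votes;
}

// Class-wise vote counts restricted to trees for which each observation is
// out-of-bag. `oob` is an n x ntree logical mask (TRUE = row i is OOB for
// tree t); `votes` as returned by tree_votes_cpp. Returns an n x k count
// matrix.
// [[Rcpp::export]]
IntegerMatrix oob_vote_counts_cpp(IntegerMatrix votes, LogicalMatrix oob,
                                  int k) {
  const int n = votes.nrow();
  const int ntree = votes.ncol();
  IntegerMatrix counts(n, k);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) {
      if (oob(i, t)) {
        counts(i, votes(i, t) - 1) += 1;
      }
    }
  }
  return counts;
}
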