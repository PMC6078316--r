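# Independent oracles used across tests.

# Exhaustive-enumeration pmf of the class-1 count in a without-replacement
# subsample of size m from n1 class-1 and n2 class-2 items. Enumerates all
# choose(n1 + n2, m) subsets; only feasible for small n1 + n2.
enum_class_pmf <- function(n1, n2, m) {
  labels <- rep(1:2, c(n1, n2))
  if (m == 0) return(c(`0` = 1))
  subsets <- utils::combn(n1 + n2, m)
  counts <- apply(subsets, 2, function(idx) sum(labels[idx] == 1))
  table(factor(counts, levels = 0:min(m, n1))) / ncol(subsets)
}

# Balanced binary null-case dataset: n observations, p iid N(0,1) features.
null_dataset <- function(n, p, props = c(0.5, 0.5)) {
  generate_dataset(simulation_design(n, p, class_proportions = props))
}

# Row subset that may drop a class entirely (bypasses the constructor's
# every-class-present invariant, for degenerate-input tests).
subset_rows_for_test <- function(ds, idx) {
  oobias:::subset_rows(ds, idx)
}

# A forest whose trees are all grown on rows of one class only, so every
# tree is a single pure leaf and the ensemble predicts that class
# constantly.
constant_forest <- function(ds, class, ntree = 10) {
  rows <- which(ds$labels == class)
  subforest(ds, mtry = 1, ntree = ntree,
            inbag = replicate(ntree, rows, simplify = FALSE))
}
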