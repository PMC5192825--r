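# Shared fixtures and independent oracles.  Everything is built in code;
# no stored data files.

# the 4-taxon, 300-Myr reference tree used throughout the rate tests
ref_tree4 <- function() parse_newick("((A:50,B:50):50,(C:50,D:50):50);")

# reduced configuration that keeps ensemble tests inside the time budget
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_submodels = 5L, n_trees = 10L,
                                 n_inner_bootstraps = 15L), list(...))
  do.call(evo_config, args)
}

# exhaustive-minimization parsimony oracle: enumerates every assignment of
# observed states to internal nodes (an optimal unweighted-parsimony labeling
# always exists within the observed states) and counts mismatched edges.
# Vectorized over assignments; fine for trees with <= 6 leaves.
brute_parsimony <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  obs <- unique(unname(states[tree$tip.label]))
  tip_states <- match(states[tree$tip.label], obs)
  grids <- rep(list(seq_along(obs)), nnode)
  A <- as.matrix(expand.grid(grids))
  F <- cbind(matrix(tip_states, nrow(A), ntip, byrow = TRUE), A)
  mism <- vapply(seq_len(nrow(tree$edge)), function(e)
    F[, tree$edge[e, 1]] != F[, tree$edge[e, 2]], logical(nrow(F)))
  min(rowSums(matrix(mism, nrow = nrow(F))))
}

# random ungapped column over a restricted alphabet, keyed by tree tips
random_column <- function(tree, n_states = 4L) {
  aa <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n_states)
  stats::setNames(sample(aa, length(tree$tip.label), replace = TRUE),
                  tree$tip.label)
}

# standard synthetic cohort for pipeline tests
pilot_cohort <- function(seed, m = 200, p = 100, n_informative = 5,
                         effect_size = 1, ...) {
  simulate_cohort(m = m, p = p, n_informative = n_informative,
                  effect_size = effect_size, class_balance = 0.3,
                  conservation_coupling = 0.9, seed = seed, ...)
}

# ensemble-level recovery: fraction of planted features used by more than
# half of the submodels
ensemble_recall <- function(model, truth) {
  u <- feature_usage(model)
  mean(truth %in% u$feature_id[u$fraction > 0.5])
}

# recall at matched sparsity: planted fraction among each model's top-k
# most-used features
recall_at_k <- function(model, truth, k) {
  u <- feature_usage(model)
  mean(truth %in% head(u$feature_id, k))
}
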