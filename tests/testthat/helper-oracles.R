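# Independent oracles and shared fixture builders for the test suite.

# Exhaustive ancestral-state enumeration: sums the joint probability of
# every assignment of internal-node states (feasible for <= 4 leaves).
# Independent of the pruning recursion it checks.
brute_force_site_lik <- function(tv, P_edges, pi, site_states) {
  n_nodes <- tv$n_tip + tv$n_node
  internal <- (tv$n_tip + 1):n_nodes
  grid <- as.matrix(expand.grid(rep(list(seq_along(pi)),
                                    length(internal))))
  A <- matrix(NA_integer_, nrow(grid), n_nodes)
  A[, internal] <- grid
  for (i in seq_len(tv$n_tip)) A[, i] <- site_states[i]
  pr <- pi[A[, tv$root]]
  for (e in seq_len(nrow(tv$edge))) {
    cc <- A[, tv$edge[e, 2]]
    if (all(is.na(cc))) next  # missing leaf: marginalizes to 1
    pr <- pr * P_edges[[e]][cbind(A[, tv$edge[e, 1]], cc)]
  }
  sum(pr)
}

# Step-up rejection-set definition of Benjamini-Hochberg: at level
# alpha, reject all p-values <= the largest p_(k) with p_(k) <= alpha*k/m.
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  s <- sort(p)
  k <- which(s <= alpha * seq_len(m) / m)
  if (!length(k)) return(rep(FALSE, m))
  p <= s[max(k)]
}

# Quadrature oracle for beta bin conditional means
beta_bin_means_oracle <- function(p, q, K) {
  edges <- qbeta(seq(0, 1, length.out = K + 1), p, q)
  vapply(seq_len(K), function(i) {
    stats::integrate(function(x) x * dbeta(x, p, q), edges[i],
                     edges[i + 1], rel.tol = 1e-10)$value * K
  }, 0)
}

# small shared fixtures
uniform_pi <- function() codon_frequencies(mode = "uniform")

random_rooted_tree <- function(n_tip) {
  tr <- ape::rtree(n_tip)
  codonsel::as_tagged_phylo(tr)
}

# exact mixture log-likelihood at given model parameters (independent
# route used to cross-check curve-based fits)
exact_model_loglik <- function(aln, tree, model, kappa, pi,
                               calibration) {
  csl <- class_site_likelihoods(aln, tree, model_class_spec(model),
                                kappa, pi, calibration = calibration)
  mixture_log_likelihood(csl)
}

# pick a clade (not spanning the root) from a tagged tree
some_proper_clade <- function(tp) {
  tr <- tp$tree
  inner <- tr$edge[tr$edge[, 2] > ape::Ntip(tr), 2]
  ape::extract.clade(tr, inner[1])$tip.label
}
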