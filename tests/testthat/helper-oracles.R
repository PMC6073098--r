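# Independent brute-force oracles and small fixtures shared across tests.

# Random ultrametric (coalescent) tree, deterministic per seed.
random_coal_tree <- function(n, seed) {
  set.seed(seed)
  ape::rcoal(n)
}

# Root-to-tip node paths by parent-link walking (independent of any
# covariance code): list, per tip, of the node indices from tip to root.
tip_paths <- function(tree) {
  n <- ape::Ntip(tree)
  n_all <- n + tree$Nnode
  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  lapply(seq_len(n), function(tp) {
    path <- tp
    p <- tp
    while (p != root) {
      p <- parent[p]
      path <- c(path, p)
    }
    path
  })
}

# MRCA depths by path intersection: oracle for phylo_covariance().
mrca_depth_oracle <- function(tree) {
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  paths <- tip_paths(tree)
  M <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    M[i, j] <- max(depth[shared])
  }
  M
}

# Patristic distances from tip depths and MRCA depths.
patristic_oracle <- function(tree) {
  C <- mrca_depth_oracle(tree)
  d <- diag(C)
  outer(d, d, "+") - 2 * C
}

# Dense multivariate-normal log density, written independently of
# gaussian_loglik (explicit inverse and log-determinant).
naive_mvn_loglik <- function(x, mu, V) {
  n <- length(x)
  r <- x - mu
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V) %*% r))
}

# Rebuild a fitted model's covariance from its reported parameters.
fit_covariance <- function(fit, tree) {
  ord <- sort(tree$tip.label, method = "radix")
  switch(fit$model,
         BM = fit$sigma_sq * phylo_covariance(tree, ord),
         WN = diag(fit$sigma_sq, ape::Ntip(tree)),
         OU = fit$sigma_sq * leafevo:::ou_structure(
           phylo_covariance(tree, ord), patristic_matrix(tree, ord),
           fit$alpha))
}

# A single valid measurement row with overridable fields.
make_leaf <- function(species = "sp1", sample_id = "s1", leaf_id = "l1",
                      A = 10, P = 16, Pi = 16, removed = 10,
                      maj = 6, min = 3, n1 = 0, n2 = 0) {
  data.frame(species = species, sample_id = sample_id, leaf_id = leaf_id,
             blade_area_cm2 = A, perimeter_cm = P,
             internal_perimeter_cm = Pi, teeth_removed_area_cm2 = removed,
             major_axis_cm = maj, minor_axis_cm = min,
             n_primary_teeth = n1, n_secondary_teeth = n2,
             stringsAsFactors = FALSE)
}
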