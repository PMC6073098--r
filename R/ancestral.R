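## Ancestral state reconstruction for continuous traits under Brownian
## motion, and the (time, trait) coordinates used to draw traitgrams.

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Joint ML reconstruction: the internal-node states minimize the
#' branch-weighted sum of squared changes
#' `sum over edges of (state_parent - state_child)^2 / branch_length`,
#' which makes every internal state the 1/length-weighted average of its
#' neighbours' states. This is a sparse linear (weighted-Laplacian) system
#' solved exactly; the root estimate coincides with the GLS root state of
#' [fit_bm()]. Zero-length branches make the weights infinite and are
#' rejected — collapse them before reconstructing.
#'
#' @param x Named numeric trait vector (names are tip labels), or unnamed in
#'   the tree's alphabetical tip order.
#' @param tree A `phylo` object with strictly positive branch lengths.
#' @return An `ancestral_states` data frame: `node` (ape node number),
#'   `label` (tip label or `""`), `parent` (ape node number, `NA` at the
#'   root), `height` (time from root), `state`, `is_tip`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ml_ancestral_bm(c(A = 0, B = 0, C = 3), tr)
#' @export
ml_ancestral_bm <- function(x, tree) {
  validate_tree(tree)
  if (any(tree$edge.length <= 0))
    stop("all branch lengths must be > 0 for ancestral reconstruction; ",
         "collapse zero-length branches first", call. = FALSE)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  x <- align_trait(x, tree$tip.label)
  ## weighted graph Laplacian over all nodes, weights 1/branch_length
  w <- 1 / tree$edge.length
  L <- matrix(0, n_all, n_all)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    L[i, i] <- L[i, i] + w[e]; L[j, j] <- L[j, j] + w[e]
    L[i, j] <- L[i, j] - w[e]; L[j, i] <- L[j, i] - w[e]
  }
  tips <- seq_len(n_tip)
  internal <- (n_tip + 1L):n_all
  rhs <- -L[internal, tips, drop = FALSE] %*% x
  states_int <- tryCatch(
    solve(L[internal, internal, drop = FALSE], rhs),
    error = function(e) stop("singular reconstruction system", call. = FALSE))
  states <- c(x, as.vector(states_int))
  heights <- ape::node.depth.edgelength(tree)
  parent <- rep(NA_integer_, n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  out <- data.frame(
    node = seq_len(n_all),
    label = c(tree$tip.label, rep("", tree$Nnode)),
    parent = parent,
    height = heights,
    state = as.numeric(states),
    is_tip = seq_len(n_all) <= n_tip)
  structure(out, class = c("ancestral_states", "data.frame"))
}

#' Traitgram coordinates for a tree and trait
#'
#' Projects the phylogeny into (time, trait) space: every node gets an x
#' coordinate equal to its height (time from the root) and a y coordinate
#' equal to its observed (tips) or reconstructed (internal nodes) state;
#' edges mirror the tree topology. On an ultrametric tree all tips plot at
#' the tree depth.
#'
#' @param tree A `phylo` object.
#' @param x Named numeric trait vector (tips).
#' @param anc Optional precomputed [ml_ancestral_bm()] result for the same
#'   tree and trait; computed if missing.
#' @return A `traitgram_data` list: `nodes` (the `ancestral_states` frame)
#'   and `edges` (data frame `parent`, `child`).
#' @export
traitgram_data <- function(tree, x, anc = NULL) {
  validate_tree(tree)
  if (is.null(anc)) anc <- ml_ancestral_bm(x, tree)
  if (!inherits(anc, "ancestral_states"))
    stop("'anc' must come from ml_ancestral_bm()", call. = FALSE)
  n_all <- ape::Ntip(tree) + tree$Nnode
  if (nrow(anc) != n_all)
    stop("'anc' does not match the tree (node count differs)", call. = FALSE)
  x <- align_trait(x, tree$tip.label)
  if (max(abs(anc$state[seq_along(x)] - x)) > 1e-12)
    stop("'anc' was computed from a different trait vector", call. = FALSE)
  edges <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2])
  structure(list(nodes = anc, edges = edges), class = "traitgram_data")
}

#' Plot a traitgram
#'
#' @param x A `traitgram_data`.
#' @param ... Passed to [plot()].
#' @export
plot.traitgram_data <- function(x, ...) {
  nd <- x$nodes
  plot(range(nd$height), range(nd$state), type = "n",
       xlab = "time from root", ylab = "trait value", ...)
  graphics::segments(nd$height[x$edges$parent], nd$state[x$edges$parent],
                     nd$height[x$edges$child], nd$state[x$edges$child],
                     col = "grey40")
  tip <- nd[nd$is_tip, ]
  graphics::points(tip$height, tip$state, pch = 16, cex = 0.7)
  graphics::text(tip$height, tip$state, tip$label, pos = 4, cex = 0.6)
  invisible(x)
}

#' Export ancestral states or traitgram coordinates to CSV
#'
#' @param anc An `ancestral_states` data frame.
#' @param file Output path.
#' @export
write_ancestral_csv <- function(anc, file) {
  stopifnot(inherits(anc, "ancestral_states"))
  write.csv(as.data.frame(anc), file, row.names = FALSE)
  invisible(file)
}
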