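## Tree input/output and the tree-derived matrices (phylogenetic covariance,
## patristic distances, lambda transform) consumed by every inference stage.
## Trees are ape "phylo" objects throughout; branch lengths are in time units
## (My for a chronogram) and all downstream outputs are unit-agnostic.

#' Read and validate a rooted phylogeny from Newick
#'
#' Parses a Newick string or file into an [ape::read.tree()] `phylo` object
#' and enforces the contract the rest of the package relies on: a single
#' rooted tree, unique non-empty tip labels, and a branch length on every
#' edge, none negative. Quoted labels and bracket comments are accepted (and
#' comments dropped) as in standard Newick; internal node labels are kept but
#' ignored; polytomies are allowed.
#'
#' @param x A Newick string, or the path of a file containing one tree.
#' @return An object of class `phylo`.
#' @seealso [write_newick()], [phylo_covariance()], [patristic_matrix()]
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tree_depth(tr)
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  text <- if (file.exists(x) && !grepl("\\(", x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else x
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not parse Newick input", call. = FALSE)
  validate_tree(tree)
  tree
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  validate_tree(tree)
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

## Internal contract check shared by every tree-consuming entry point.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip label", call. = FALSE)
  if (anyDuplicated(labs))
    stop("duplicate tip labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have a branch length on every edge", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  invisible(tree)
}

#' Root-to-tip depth of a phylogeny
#'
#' @param tree A `phylo` object.
#' @return The maximum root-to-tip distance (time units of the tree).
#' @export
tree_depth <- function(tree) {
  validate_tree(tree)
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Is a tree ultrametric (a chronogram)?
#'
#' Tip depths are compared with a tolerance relative to the tree depth
#' (default 1e-6), the scale at which dating software rounds edge lengths.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on `max(depth) - min(depth)`.
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  validate_tree(tree)
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= tol * max(d)
}

## Default tip order for all matrices: alphabetical, unless caller overrides.
default_tip_order <- function(tree) sort(tree$tip.label, method = "radix")

check_tip_order <- function(tree, tip_order) {
  if (is.null(tip_order)) return(default_tip_order(tree))
  if (!setequal(tip_order, tree$tip.label) ||
      length(tip_order) != ape::Ntip(tree))
    stop("'tip_order' must be a permutation of the tree's tip labels",
         call. = FALSE)
  tip_order
}

#' Phylogenetic (Brownian) covariance matrix
#'
#' Entry (i, j) is the depth of the most recent common ancestor of tips i and
#' j, i.e. the shared root-to-tip path length; the diagonal holds the tip
#' depths. Under Brownian motion with rate `sigma_sq` the trait covariance
#' between tips is `sigma_sq` times this matrix. On an ultrametric tree the
#' diagonal is constant and equal to the tree depth.
#'
#' @param tree A `phylo` object.
#' @param tip_order Optional character vector giving the row/column order;
#'   defaults to alphabetical tip labels. The order is carried in dimnames.
#' @return A symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree, tip_order = NULL) {
  validate_tree(tree)
  tip_order <- check_tip_order(tree, tip_order)
  C <- ape::vcv.phylo(tree)
  C[tip_order, tip_order, drop = FALSE]
}

#' Patristic distance matrix
#'
#' Entry (i, j) is the sum of branch lengths along the path joining tips i
#' and j. On an ultrametric tree of depth T this equals `2 * (T - C_ij)`
#' where C is the phylogenetic covariance; on any tree,
#' `D_ij = C_ii + C_jj - 2 C_ij`.
#'
#' @inheritParams phylo_covariance
#' @return A symmetric nonnegative matrix with zero diagonal and tip labels
#'   as dimnames.
#' @export
patristic_matrix <- function(tree, tip_order = NULL) {
  validate_tree(tree)
  tip_order <- check_tip_order(tree, tip_order)
  D <- ape::cophenetic.phylo(tree)
  D[tip_order, tip_order, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries (shared history) by `lambda` while
#' preserving the diagonal exactly. `lambda = 1` returns the Brownian
#' expectation unchanged; `lambda = 0` removes all between-species
#' correlation, leaving a diagonal matrix of tip depths.
#'
#' @param C A phylogenetic covariance matrix (see [phylo_covariance()]).
#' @param lambda Scaling of between-species correlation, in `[0, 1]`.
#' @return The transformed matrix, same dimnames.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop("'C' must be a square matrix", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("'lambda' must be a single value in [0, 1]", call. = FALSE)
  d <- diag(C)
  Cl <- C * lambda
  diag(Cl) <- d
  Cl
}

#' Restrict a tree to a subset of tips
#'
#' Drops all tips not in `keep`, collapsing unbranched internal paths and
#' summing their branch lengths, so that patristic distances among the kept
#' tips are unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return A `phylo` object with tips `keep`.
#' @export
prune_to <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("labels not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(keep) < 2L)
    stop("at least 2 tips must be kept", call. = FALSE)
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Export a tip-by-tip matrix as CSV
#'
#' Writes the matrix with its tip order as header row and first column, the
#' interchange format used by the pipeline.
#'
#' @param m A matrix with tip labels as dimnames.
#' @param file Output path.
#' @export
write_matrix_csv <- function(m, file) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  df <- data.frame(tip = rownames(m), m, check.names = FALSE)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
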