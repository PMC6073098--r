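## Phylogenetic Signal Representation (PSR) curves: eigenvectors of the
## double-centered patristic distance matrix are used, successively, as OLS
## regressors for a trait; plotting R^2 against the cumulative eigenvalue
## fraction yields a curve whose 45-degree diagonal corresponds to Brownian
## evolution — curves below it indicate slower-than-Brownian (OU-like)
## evolution, curves above it early, faster-than-Brownian diversification.
##
## Note on the centering: patristic distances already behave as SQUARED
## Euclidean distances of the Brownian embedding of the tips
## (D_ij = C_ii + C_jj - 2 C_ij, with C the phylogenetic covariance), so the
## Gower centering is applied to D itself, -J D J / 2 = J C J. This is what
## ties the cumulative eigenvalue fraction to the expected explained variance
## of a Brownian trait and hence puts Brownian motion on the diagonal.

#' Phylogenetic eigenvector basis from a patristic distance matrix
#'
#' Double-centers the patristic distance matrix
#' (`B = -0.5 * J %*% D %*% J`, `J = I - 11'/n`) and eigen-decomposes it.
#' Eigenpairs with eigenvalue above `cutoff * max(eigenvalue)` are retained
#' in descending order; a materially negative eigenvalue (below
#' `-1e-8 * max`) indicates a corrupted distance matrix and is an error.
#'
#' @param D A patristic distance matrix (see [patristic_matrix()]) with tip
#'   labels as dimnames, or a `phylo` object from which it is computed.
#' @param cutoff Relative retention threshold for eigenvalues.
#' @return A `phylo_eigenbasis` list: `vectors` (n x m, orthonormal columns),
#'   `values` (length m, descending, positive), `tip_order`, `total`
#'   (sum of retained eigenvalues).
#' @export
phylo_eigenbasis <- function(D, cutoff = 1e-10) {
  if (inherits(D, "phylo")) D <- patristic_matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 4) stop("at least 4 tips are required", call. = FALSE)
  if (is.null(rownames(D)))
    stop("'D' must carry tip labels as dimnames", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8 * max(abs(D)))
    stop("'D' is not symmetric", call. = FALSE)
  B <- -0.5 * D
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  emax <- max(e$values)
  if (emax <= 0) stop("no positive eigenvalues", call. = FALSE)
  if (min(e$values) < -1e-8 * emax)
    stop("materially negative eigenvalue: input is not a tree metric",
         call. = FALSE)
  keep <- e$values > cutoff * emax
  if (!any(keep)) stop("all eigenvalues below cutoff", call. = FALSE)
  structure(list(vectors = e$vectors[, keep, drop = FALSE],
                 values = e$values[keep],
                 tip_order = rownames(D),
                 total = sum(e$values[keep])),
            class = "phylo_eigenbasis")
}

#' @export
print.phylo_eigenbasis <- function(x, ...) {
  cat(sprintf("phylogenetic eigenbasis: %d tips, %d eigenvectors\n",
              length(x$tip_order), length(x$values)))
  cat("  leading eigenvalue fractions:",
      paste(sprintf("%.3f", head(x$values / x$total, 5)), collapse = " "),
      "\n")
  invisible(x)
}

#' Phylogenetic signal representation curve of a trait
#'
#' For each k, regresses the trait by OLS (with intercept) on the first k
#' phylogenetic eigenvectors and records the coefficient of determination
#' R^2 against the cumulative eigenvalue fraction
#' `xi_k = sum(values[1:k]) / sum(values)`. The signed area is the
#' trapezoidal integral of `R^2(xi) - xi` over `[0, 1]`, including the
#' origin: positive above the Brownian diagonal (early, faster-than-Brownian
#' diversification), negative below it (slower, OU-like evolution).
#'
#' @param x Named numeric trait vector aligned to `basis$tip_order` by name.
#' @param basis A `phylo_eigenbasis`.
#' @return A `psr_curve` list: `points` (data frame `k`, `xi`, `r_squared`)
#'   and `area`.
#' @export
psr_curve <- function(x, basis) {
  stopifnot(inherits(basis, "phylo_eigenbasis"))
  x <- align_trait(x, basis$tip_order)
  xc <- x - mean(x)
  tot <- sum(xc^2)
  if (tot <= 0) stop("constant trait has no PSR curve", call. = FALSE)
  ## eigenvectors are orthonormal and centered, so sequential OLS R^2 is a
  ## cumulative sum of squared projections
  proj <- as.vector(crossprod(basis$vectors, xc))^2
  r2 <- pmin(cumsum(proj) / tot, 1)
  xi <- cumsum(basis$values) / basis$total
  pts <- data.frame(k = seq_along(xi), xi = xi, r_squared = r2)
  xs <- c(0, xi)
  ys <- c(0, r2 - xi)
  area <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  structure(list(points = pts, area = area), class = "psr_curve")
}

#' @export
print.psr_curve <- function(x, ...) {
  cat(sprintf("PSR curve: %d points, signed area vs 45-degree line = %.4f\n",
              nrow(x$points), x$area))
  invisible(x)
}

#' Monte-Carlo PSR envelope under a generating model
#'
#' Simulates traits on the tree under white noise or Brownian motion (unit
#' rate), computes each replicate's PSR curve on the tree's eigenbasis, and
#' returns pointwise mean and quantile bands. Under white noise the analytic
#' mean R^2 at step k is `k / (n - 1)`, available as a cross-check; the
#' Brownian mean tracks the 45-degree diagonal.
#'
#' @param tree A `phylo` object.
#' @param model `"WN"` or `"BM"`.
#' @param n_sims Number of simulations (at least 99).
#' @param seed Integer seed; identical seeds give identical envelopes.
#' @param probs Lower/upper band quantiles.
#' @return A `psr_envelope` list: `band` (data frame `k`, `xi`, `lower`,
#'   `mean`, `upper`), `areas` (per-replicate signed areas), `model`,
#'   `n_sims`, `seed`.
#' @export
psr_envelope <- function(tree, model = c("WN", "BM"), n_sims = 999, seed = 1,
                         probs = c(0.025, 0.975)) {
  model <- match.arg(model)
  if (n_sims < 99) stop("'n_sims' must be at least 99", call. = FALSE)
  validate_tree(tree)
  basis <- phylo_eigenbasis(patristic_matrix(tree))
  X <- simulate_traits(tree, model = model, n_reps = n_sims, seed = seed)
  m <- length(basis$values)
  r2 <- matrix(0, n_sims, m)
  areas <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    cv <- psr_curve(X[, i], basis)
    r2[i, ] <- cv$points$r_squared
    areas[i] <- cv$area
  }
  band <- data.frame(
    k = seq_len(m),
    xi = cumsum(basis$values) / basis$total,
    lower = apply(r2, 2, quantile, probs = probs[1]),
    mean = colMeans(r2),
    upper = apply(r2, 2, quantile, probs = probs[2]))
  structure(list(band = band, areas = areas, model = model,
                 n_sims = n_sims, seed = seed),
            class = "psr_envelope")
}

#' @export
print.psr_envelope <- function(x, ...) {
  cat(sprintf("PSR %s envelope: %d simulations (seed %s), mean area %.4f\n",
              x$model, x$n_sims, format(x$seed), mean(x$areas)))
  invisible(x)
}

#' Plot a PSR curve against the Brownian diagonal
#'
#' Base-graphics rendering of a curve, the 45-degree Brownian reference
#' line, and (optionally) a simulated envelope band.
#'
#' @param x A `psr_curve`.
#' @param envelope Optional `psr_envelope` drawn as a shaded band.
#' @param ... Passed to [plot()].
#' @export
plot.psr_curve <- function(x, envelope = NULL, ...) {
  plot(c(0, 1), c(0, 1), type = "n", xlab = "cumulative eigenvalue fraction",
       ylab = expression(R^2), ...)
  if (!is.null(envelope)) {
    b <- envelope$band
    graphics::polygon(c(0, b$xi, rev(b$xi), 0), c(0, b$lower, rev(b$upper), 0),
                      col = grDevices::adjustcolor("gold", 0.3), border = NA)
    graphics::lines(c(0, b$xi), c(0, b$mean), col = "goldenrod", lty = 2)
  }
  graphics::abline(0, 1, col = "grey50")
  graphics::lines(c(0, x$points$xi), c(0, x$points$r_squared), lwd = 2)
  graphics::points(x$points$xi, x$points$r_squared, pch = 16, cex = 0.6)
  invisible(x)
}
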