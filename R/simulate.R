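## Synthetic data: trees, trait vectors under each evolutionary model, and
## geometrically valid leaf-measurement tables. Every generator is a pure
## function of (parameters, seed), so the whole pipeline can be exercised
## and calibrated without herbarium material.

#' Simulate trait vectors on a tree under an evolutionary model
#'
#' Draws replicate trait vectors from the multivariate normal with constant
#' mean `z0` and the model's tip covariance: `sigma_sq * C` for Brownian
#' motion, the Hansen single-optimum form for OU, `sigma_sq * I` for white
#' noise, and `sigma_sq * C(lambda)` for the lambda transform. A single
#' covariance factorization serves all four models, which makes the
#' generator double as a likelihood cross-check: `lambda = 1` is exactly BM
#' and `lambda = 0` is white noise up to tip-depth scaling.
#'
#' @param tree A `phylo` object with at least 4 tips (OU requires it
#'   ultrametric).
#' @param model One of `"BM"`, `"OU"`, `"WN"`, `"lambda"`.
#' @param n_reps Number of replicate vectors.
#' @param sigma_sq Rate (trait^2 per time unit; per trait for WN), > 0.
#' @param z0 Root state / optimum / mean.
#' @param alpha OU pull strength (1/time), required for `model = "OU"`.
#' @param lambda Scaling in `[0, 1]`, required for `model = "lambda"`.
#' @param seed Integer seed (mandatory; generators are pure functions of
#'   parameters and seed).
#' @return A tips x `n_reps` numeric matrix, rownames the alphabetical tip
#'   labels, with the generating parameters in attribute `spec`.
#' @export
simulate_traits <- function(tree, model = c("BM", "OU", "WN", "lambda"),
                            n_reps = 1L, sigma_sq = 1, z0 = 0,
                            alpha = NULL, lambda = NULL, seed) {
  model <- match.arg(model)
  validate_tree(tree)
  if (ape::Ntip(tree) < 4) stop("at least 4 tips are required", call. = FALSE)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (!is.numeric(sigma_sq) || sigma_sq <= 0)
    stop("'sigma_sq' must be > 0", call. = FALSE)
  ord <- default_tip_order(tree)
  n <- length(ord)
  V <- switch(model,
    BM = sigma_sq * phylo_covariance(tree, ord),
    WN = diag(sigma_sq, n),
    OU = {
      if (is.null(alpha) || alpha <= 0)
        stop("'alpha' > 0 is required for the OU model", call. = FALSE)
      if (!is_ultrametric_tree(tree))
        stop("OU simulation requires an ultrametric tree", call. = FALSE)
      sigma_sq * ou_structure(phylo_covariance(tree, ord),
                              patristic_matrix(tree, ord), alpha)
    },
    lambda = {
      if (is.null(lambda))
        stop("'lambda' in [0, 1] is required for the lambda model",
             call. = FALSE)
      sigma_sq * lambda_transform(phylo_covariance(tree, ord), lambda)
    })
  ## chol() tolerates the PSD-but-singular lambda = 0 boundary via pivoting
  ch <- suppressWarnings(chol(V, pivot = TRUE))
  piv <- attr(ch, "pivot")
  rk <- attr(ch, "rank")
  Lt <- matrix(0, n, n)
  Lt[seq_len(rk), piv] <- ch[seq_len(rk), ]
  X <- with_seed(seed, {
    Z <- matrix(rnorm(n * n_reps), n, n_reps)
    z0 + crossprod(Lt, Z[seq_len(n), , drop = FALSE])
  })
  dimnames(X) <- list(ord, NULL)
  attr(X, "spec") <- list(model = model, sigma_sq = sigma_sq, z0 = z0,
                          alpha = alpha, lambda = lambda,
                          n_reps = n_reps, seed = seed)
  X
}

#' Deterministic clade-structured ultrametric fixture tree
#'
#' Builds an ultrametric tree of exactly the requested depth whose tips are
#' partitioned into monophyletic clades, emulating a family-level chronogram
#' (default: 27 species in four subgeneric clades of sizes 7, 6, 5 and 9,
#' crown depth 80 time units). The clades hang off a short backbone ladder
#' (splits within the first quarter of the depth, mimicking an early
#' radiation) and each clade crown is a coalescent topology rescaled so
#' that the clade crowns sit at 55% of the tree depth — long subtending
#' stems, as in the study system. Deterministic per seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param n_clades Number of monophyletic clades (>= 1, <= `n_tips`).
#' @param depth Root-to-tip depth in time units.
#' @param clade_sizes Optional integer partition of `n_tips` into
#'   `n_clades`; defaults to `c(7, 6, 5, 9)` for the 27/4 default, else a
#'   near-even split.
#' @param seed Integer seed.
#' @return An ultrametric `phylo` object with tips `s01`, `s02`, ...
#' @export
fixture_tree <- function(n_tips = 27L, n_clades = 4L, depth = 80,
                         clade_sizes = NULL, seed = 1L) {
  n_tips <- as.integer(n_tips); n_clades <- as.integer(n_clades)
  if (n_tips < 2) stop("'n_tips' must be at least 2", call. = FALSE)
  if (n_clades < 1) stop("'n_clades' must be at least 1", call. = FALSE)
  n_clades <- min(n_clades, n_tips)
  if (is.null(clade_sizes)) {
    clade_sizes <- if (n_tips == 27L && n_clades == 4L) c(7L, 6L, 5L, 9L)
    else {
      base <- n_tips %/% n_clades
      sz <- rep(base, n_clades)
      extra <- n_tips - sum(sz)
      if (extra > 0) sz[seq_len(extra)] <- sz[seq_len(extra)] + 1L
      sz
    }
  }
  if (sum(clade_sizes) != n_tips || any(clade_sizes < 1))
    stop("'clade_sizes' must be a positive partition of 'n_tips'",
         call. = FALSE)
  labels <- sprintf("s%02d", seq_len(n_tips))
  lab_groups <- split(labels, rep(seq_len(n_clades), clade_sizes))
  if (n_clades == 1L) {
    tree <- if (n_tips == 2L) {
      read_newick(sprintf("(%s:%s,%s:%s);", labels[1], depth,
                          labels[2], depth))
    } else {
      with_seed(seed, {
        t1 <- ape::rcoal(n_tips, tip.label = labels)
        t1$edge.length <- t1$edge.length /
          max(ape::node.depth.edgelength(t1)) * depth
        t1
      })
    }
    return(validate_tree(tree))
  }
  crown_depth <- 0.55 * depth        # clade crown nodes sit here
  ## backbone ladder (c1,(c2,(...,cK))): splits at depths 0, h, 2h, ...,
  ## all within the first quarter of the depth (an early radiation); clade
  ## i attaches at depth a_i = (i-1)*h, the last clade at (K-2)*h
  h <- (0.25 * depth) / (n_clades - 1)
  attach_depth <- function(i)
    if (i == n_clades) (n_clades - 2) * h else (i - 1) * h
  clade_newick <- function(labs, a) {
    if (length(labs) == 1L)
      return(paste0(labs, ":", format(depth - a, digits = 15)))
    sub_tree <- ape::rcoal(length(labs), tip.label = labs)
    sub_tree$edge.length <- sub_tree$edge.length /
      max(ape::node.depth.edgelength(sub_tree)) * (depth - crown_depth)
    s <- sub(";$", "", ape::write.tree(sub_tree))
    paste0(s, ":", format(crown_depth - a, digits = 15))
  }
  nwk <- with_seed(seed, {
    parts <- lapply(seq_len(n_clades), function(i)
      clade_newick(lab_groups[[i]], attach_depth(i)))
    out <- parts[[n_clades]]
    for (i in rev(seq_len(n_clades - 1L)))
      out <- paste0("(", parts[[i]], ",", out,
                    if (i > 1) paste0("):", format(h, digits = 15)) else ");")
    out
  })
  tree <- read_newick(nwk)
  ## exact-depth correction for printed-precision slop
  d <- ape::node.depth.edgelength(tree)[seq_len(n_tips)]
  stopifnot(max(d) - min(d) < 1e-8 * depth)
  tree
}

#' Example per-species leaf generator parameters
#'
#' Convenience parameter table for [simulate_leaf_measurements()]: species
#' vary smoothly in blade area, circularity and toothiness, and roughly a
#' quarter of them (the tail of the list, mimicking a tropical entire-margin
#' clade) are untoothed.
#'
#' @param species Character vector of species names.
#' @param seed Integer seed.
#' @return Data frame of generator parameters, one row per species.
#' @export
example_species_params <- function(species, seed = 1L) {
  n <- length(species)
  with_seed(seed, {
    untoothed <- seq_len(n) > ceiling(0.75 * n)
    data.frame(
      species = species,
      mean_area_cm2 = exp(runif(n, log(1.5), log(40))),
      shape_factor = runif(n, 0.45, 0.85),
      aspect_ratio = runif(n, 1.1, 2.2),
      tooth_density_per_cm = ifelse(untoothed, 0, runif(n, 0.5, 3)),
      secondary_per_primary = ifelse(untoothed, 0, runif(n, 0.2, 1.2)),
      tooth_area_frac = ifelse(untoothed, 0, runif(n, 0.02, 0.12)),
      sd_log_area = 0.25,
      stringsAsFactors = FALSE)
  })
}

#' Simulate geometrically valid leaf measurement records
#'
#' Generates per-leaf raw measurements by drawing each leaf in a shape
#' parameterization — blade area, shape factor, aspect ratio, tooth density
#' and relative tooth area — and inverting it to the measured quantities
#' (perimeter from the shape factor, axis lengths from an elliptical aspect
#' ratio). Working in that parameterization guarantees the geometric
#' invariants by construction: `P^2 >= 4*pi*A` (shape factor at most 1),
#' `FerDiam <= MajLen`, `Pi <= P`, and untoothed leaves with `Pi = P` and
#' `teeth_removed_area = A`. Leaves are grouped into samples of 5-6, the
#' usual herbarium-sheet yield.
#'
#' @param params Data frame with columns `species`, `mean_area_cm2`,
#'   `shape_factor` (0-1), `aspect_ratio` (>= 1), `tooth_density_per_cm`
#'   (primary teeth per cm of perimeter; 0 = untoothed),
#'   `secondary_per_primary`, `tooth_area_frac` (fraction of blade area in
#'   teeth) and optionally `sd_log_area` (lognormal leaf-size noise,
#'   default 0.25). See [example_species_params()].
#' @param n_leaves Leaves per species.
#' @param seed Integer seed.
#' @return A measurement data frame (schema of [measurement_columns()])
#'   that passes [validate_measurements()] with zero problems.
#' @export
simulate_leaf_measurements <- function(params, n_leaves = 30L, seed = 1L) {
  need <- c("species", "mean_area_cm2", "shape_factor", "aspect_ratio",
            "tooth_density_per_cm", "secondary_per_primary",
            "tooth_area_frac")
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("'params' lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(params$shape_factor <= 0 | params$shape_factor > 1))
    stop("'shape_factor' must be in (0, 1]", call. = FALSE)
  if (any(params$aspect_ratio < 1))
    stop("'aspect_ratio' must be >= 1", call. = FALSE)
  if (any(params$tooth_area_frac < 0 | params$tooth_area_frac > 0.4))
    stop("'tooth_area_frac' must be in [0, 0.4]", call. = FALSE)
  if (is.null(params$sd_log_area)) params$sd_log_area <- 0.25
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      A <- p$mean_area_cm2 * exp(rnorm(n_leaves, 0, p$sd_log_area))
      sf <- plogis(qlogis(p$shape_factor) + rnorm(n_leaves, 0, 0.15))
      ar <- 1 + (p$aspect_ratio - 1) * exp(rnorm(n_leaves, 0, 0.1))
      P <- sqrt(4 * pi * A / sf)
      fer <- 2 * sqrt(A / pi)
      maj <- fer * sqrt(ar)
      min_ <- fer / sqrt(ar)
      toothed <- p$tooth_density_per_cm > 0
      n1 <- if (toothed) pmax(rpois(n_leaves, p$tooth_density_per_cm * P), 1L)
            else integer(n_leaves)
      n2 <- if (toothed) rpois(n_leaves, n1 * p$secondary_per_primary)
            else integer(n_leaves)
      taf <- if (toothed)
        pmin(pmax(p$tooth_area_frac * exp(rnorm(n_leaves, 0, 0.2)), 0), 0.45)
        else numeric(n_leaves)
      TA <- taf * A
      ## tooth removal shortens the outline: a fraction tied to tooth area
      pif <- if (toothed) pmin(0.6 * taf + abs(rnorm(n_leaves, 0, 0.02)), 0.5)
             else numeric(n_leaves)
      data.frame(
        species = p$species,
        sample_id = paste0(p$species, "_smp",
                           sprintf("%02d", ((seq_len(n_leaves) - 1) %/%
                                              sample(5:6, 1)) + 1)),
        leaf_id = paste0(p$species, "_leaf",
                         sprintf("%03d", seq_len(n_leaves))),
        blade_area_cm2 = A,
        perimeter_cm = P,
        internal_perimeter_cm = P * (1 - pif),
        teeth_removed_area_cm2 = A - TA,
        major_axis_cm = maj,
        minor_axis_cm = min_,
        n_primary_teeth = as.integer(n1),
        n_secondary_teeth = as.integer(n2),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Simulation-based recovery experiment
#'
#' Simulates replicate traits on a tree under one generating model and runs
#' the full inference battery on each: Pagel's lambda ([fit_lambda()]),
#' BM/OU/WN comparison ([compare_models()]) and the PSR curve
#' ([psr_curve()]). Used to calibrate what the estimators recover under
#' known conditions.
#'
#' @inheritParams simulate_traits
#' @return A `recovery_experiment` list: `summary` (`median_lambda`,
#'   `top_model_freq` — named frequencies over BM/OU/WN — and
#'   `mean_psr_area`) and `replicates`, a per-replicate data frame with
#'   columns `lambda`, `p_value`, `top_model`, `wAIC_BM`, `wAIC_OU`,
#'   `wAIC_WN`, `psr_area`.
#' @export
recovery_experiment <- function(tree, model = c("BM", "OU", "WN", "lambda"),
                                n_reps = 100L, sigma_sq = 1, z0 = 0,
                                alpha = NULL, lambda = NULL, seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  X <- simulate_traits(tree, model = model, n_reps = n_reps,
                       sigma_sq = sigma_sq, z0 = z0, alpha = alpha,
                       lambda = lambda, seed = seed)
  basis <- phylo_eigenbasis(patristic_matrix(tree))
  reps <- lapply(seq_len(n_reps), function(i) {
    x <- X[, i]
    sig <- fit_lambda(x, tree)
    cmp <- compare_models(x, tree)
    w <- stats::setNames(cmp$wAIC, cmp$model)
    data.frame(lambda = sig$lambda, p_value = sig$p_value,
               top_model = cmp$model[which.max(cmp$wAIC)],
               wAIC_BM = w[["BM"]], wAIC_OU = w[["OU"]], wAIC_WN = w[["WN"]],
               psr_area = psr_curve(x, basis)$area)
  })
  reps <- do.call(rbind, c(reps, list(make.row.names = FALSE)))
  freq <- table(factor(reps$top_model, levels = c("BM", "OU", "WN")))
  structure(list(
    summary = list(median_lambda = stats::median(reps$lambda),
                   top_model_freq = stats::setNames(as.numeric(freq) / n_reps,
                                                    names(freq)),
                   mean_psr_area = mean(reps$psr_area)),
    replicates = reps,
    model = model, n_reps = n_reps, seed = seed),
    class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("recovery experiment: %s model, %d replicates (seed %s)\n",
              x$model, x$n_reps, format(x$seed)))
  cat(sprintf("  median lambda-hat = %.3f   mean PSR area = %.4f\n",
              x$summary$median_lambda, x$summary$mean_psr_area))
  cat("  top-wAIC frequencies:",
      paste(sprintf("%s %.2f", names(x$summary$top_model_freq),
                    x$summary$top_model_freq), collapse = ", "), "\n")
  invisible(x)
}
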