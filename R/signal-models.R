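## Likelihood engine: Pagel's lambda with a likelihood-ratio test, and
## maximum-likelihood fits of Brownian-motion (BM), single-optimum
## Ornstein-Uhlenbeck (OU) and white-noise (WN) models compared by Akaike
## weights. All models are multivariate normal with a constant mean vector;
## they differ only in the tip covariance structure:
##   BM:     sigma_sq * C                     (C = shared branch lengths)
##   lambda: sigma_sq * C(lambda)             (off-diagonals scaled)
##   OU:     (sigma_sq/2a) e^(-a d_ij) (1 - e^(-2a s_ij))   (Hansen form)
##   WN:     sigma_sq * I
## Mean and rate are profiled analytically by GLS; only lambda / alpha need a
## 1-D bounded numeric search. Solves go through a Cholesky factorization
## (no explicit inverse); log-determinants come from the factor diagonal.

#' Multivariate-normal log-likelihood with constant mean
#'
#' Exact log density of `x` under N(mean * 1, V), evaluated via a Cholesky
#' factorization of `V`.
#'
#' @param x Numeric vector of tip values.
#' @param mean Scalar mean (root state / optimum / common mean).
#' @param V Symmetric positive-definite covariance matrix, rows/columns
#'   aligned with `x`.
#' @return The log-likelihood (scalar).
#' @export
gaussian_loglik <- function(x, mean, V) {
  n <- length(x)
  stopifnot(is.matrix(V), nrow(V) == n, ncol(V) == n)
  ch <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is singular or not positive definite",
         call. = FALSE))
  z <- backsolve(ch, x - mean, transpose = TRUE)
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * (n * log(2 * pi) + logdet + sum(z^2))
}

## GLS profile of (mu, sigma_sq) for V = sigma_sq * R: returns the profiled
## estimates and the maximized log-likelihood.
profile_gls <- function(x, R) {
  n <- length(x)
  ch <- tryCatch(chol(R), error = function(e)
    stop("covariance structure is singular or not positive definite",
         call. = FALSE))
  zx <- backsolve(ch, x, transpose = TRUE)
  z1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  mu <- sum(z1 * zx) / sum(z1 * z1)
  q <- sum((zx - mu * z1)^2)
  if (q <= 0) stop("zero residual variance: trait is constant", call. = FALSE)
  sigma_sq <- q / n
  logdetR <- 2 * sum(log(diag(ch)))
  logL <- -0.5 * (n * log(2 * pi * sigma_sq) + logdetR + n)
  list(mu = mu, sigma_sq = sigma_sq, logL = logL)
}

new_evo_fit <- function(model, sigma_sq, z0, logL, k, alpha = NA_real_) {
  structure(list(model = model, sigma_sq = sigma_sq, z0 = z0, alpha = alpha,
                 logL = logL, k = k, AIC = 2 * k - 2 * logL),
            class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("%s model fit\n", x$model))
  cat(sprintf("  sigma^2 = %.6g   z0/mu = %.6g", x$sigma_sq, x$z0))
  if (!is.na(x$alpha)) cat(sprintf("   alpha = %.6g", x$alpha))
  cat(sprintf("\n  logL = %.4f   k = %d   AIC = %.4f\n", x$logL, x$k, x$AIC))
  invisible(x)
}

#' Fit the white-noise model
#'
#' Tip values are independent and identically normal; this is the
#' phylogeny-free null. Closed form: `mu` is the sample mean, `sigma_sq` the
#' maximum-likelihood (1/n) variance, and
#' `logL = -(n/2) * (log(2*pi*sigma_sq) + 1)`. Two parameters.
#'
#' @param x Numeric trait vector (3 or more values, non-constant).
#' @return An `evo_fit` with `model = "WN"`.
#' @export
fit_wn <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("at least 3 values are required", call. = FALSE)
  mu <- mean(x)
  s2 <- sum((x - mu)^2) / n
  if (s2 <= 0) stop("zero residual variance: trait is constant", call. = FALSE)
  logL <- -0.5 * n * (log(2 * pi * s2) + 1)
  new_evo_fit("WN", s2, mu, logL, 2L)
}

#' Fit the Brownian-motion model
#'
#' Root state `z0` is the GLS mean `(1' C^-1 x) / (1' C^-1 1)` and the rate
#' is the maximum-likelihood estimate
#' `sigma_sq = (x - z0)' C^-1 (x - z0) / n`, with C the phylogenetic
#' covariance of the tree. Two parameters.
#'
#' @param x Named numeric trait vector (names are tip labels), or unnamed in
#'   the tree's alphabetical tip order.
#' @param tree A `phylo` object.
#' @return An `evo_fit` with `model = "BM"`.
#' @export
fit_bm <- function(x, tree) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 2) stop("at least 2 tips are required", call. = FALSE)
  ord <- default_tip_order(tree)
  x <- align_trait(x, ord)
  C <- phylo_covariance(tree, ord)
  pf <- profile_gls(x, C)
  new_evo_fit("BM", pf$sigma_sq, pf$mu, pf$logL, 2L)
}

## OU covariance structure (unit rate): (1/2a) e^(-a d_ij) (1 - e^(-2a s_ij))
## with s = shared root-to-MRCA time (the BM covariance) and d = patristic
## distance. As a -> 0 this tends to s (the BM structure); as a -> Inf the
## off-diagonals vanish.
ou_structure <- function(C, D, alpha) {
  exp(-alpha * D) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
}

#' Fit the single-optimum Ornstein-Uhlenbeck model
#'
#' Hansen's stabilizing-selection model with one optimum: Brownian drift plus
#' a pull of strength `alpha` (units 1/time) toward the optimum, which also
#' serves as the root state `z0`. Tip covariance
#' `V_ij = (sigma_sq / 2*alpha) * exp(-alpha*d_ij) * (1 - exp(-2*alpha*s_ij))`
#' with `s_ij` the shared time and `d_ij` the patristic distance. For each
#' `alpha`, `z0` and `sigma_sq` are profiled analytically; `alpha` itself is
#' optimized on a log scale over `[1e-9/T, 1e3/T]` (T = tree depth), seeded
#' from a coarse grid. Three parameters. Requires an ultrametric tree.
#'
#' @inheritParams fit_bm
#' @param alpha_bounds Search interval for `alpha`, default `c(1e-9, 1e3)/T`.
#' @param grid_size Number of log-spaced grid points used to bracket the
#'   optimum before refinement.
#' @return An `evo_fit` with `model = "OU"` and the fitted `alpha`.
#' @export
fit_ou <- function(x, tree, alpha_bounds = NULL, grid_size = 30L) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 4) stop("at least 4 tips are required", call. = FALSE)
  if (!is_ultrametric_tree(tree))
    stop("the OU fit requires an ultrametric tree (a chronogram)",
         call. = FALSE)
  ord <- default_tip_order(tree)
  x <- align_trait(x, ord)
  C <- phylo_covariance(tree, ord)
  D <- patristic_matrix(tree, ord)
  T_depth <- max(diag(C))
  if (is.null(alpha_bounds)) alpha_bounds <- c(1e-9, 1e3) / T_depth
  la <- log(alpha_bounds)
  obj <- function(log_alpha)
    profile_gls(x, ou_structure(C, D, exp(log_alpha)))$logL
  grid <- seq(la[1], la[2], length.out = grid_size)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  ## keep whichever of grid optimum / refined optimum is better
  if (opt$objective >= vals[i]) {
    log_alpha <- opt$maximum; logL <- opt$objective
  } else {
    log_alpha <- grid[i]; logL <- vals[i]
  }
  alpha <- exp(log_alpha)
  pf <- profile_gls(x, ou_structure(C, D, alpha))
  fit <- new_evo_fit("OU", pf$sigma_sq, pf$mu, pf$logL, 3L, alpha = alpha)
  fit
}

#' Estimate Pagel's lambda with a likelihood-ratio test
#'
#' `lambda` scales the off-diagonal (shared-history) entries of the Brownian
#' covariance: 0 means trait variation independent of phylogeny, 1 means the
#' full Brownian expectation. The profile log-likelihood over
#' `lambda in [0, 1]` (mean and rate profiled by GLS as in [fit_bm()]) is
#' maximized by a bounded 1-D search seeded from the best of an 11-point
#' grid; significance of phylogenetic signal is assessed by the likelihood
#' ratio `LR = 2 * (logL(lambda_hat) - logL(0))` referred to a chi-squared
#' distribution with 1 degree of freedom.
#'
#' @inheritParams fit_bm
#' @param grid Lambda values used to seed the search (default
#'   `seq(0, 1, by = 0.1)`).
#' @param tol Convergence tolerance of the bounded search.
#' @return A `signal_fit` list: `lambda` (in `[0, 1]`), `sigma_sq`, `z0`,
#'   `logL`, `logL0` (at lambda = 0), `LR`, `p_value`.
#' @export
fit_lambda <- function(x, tree, grid = seq(0, 1, by = 0.1), tol = 1e-8) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 4) stop("at least 4 tips are required", call. = FALSE)
  ord <- default_tip_order(tree)
  x <- align_trait(x, ord)
  C <- phylo_covariance(tree, ord)
  obj <- function(lam) profile_gls(x, lambda_transform(C, lam))$logL
  vals <- vapply(grid, obj, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(obj, interval = c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective >= vals[i]) {
    lambda <- opt$maximum; logL <- opt$objective
  } else {
    lambda <- grid[i]; logL <- vals[i]
  }
  ## snap to the boundary when the search lands within tolerance of it
  if (lambda < sqrt(tol)) {
    l0 <- obj(0); if (l0 >= logL) { lambda <- 0; logL <- l0 }
  }
  if (lambda > 1 - sqrt(tol)) {
    l1 <- obj(1); if (l1 >= logL) { lambda <- 1; logL <- l1 }
  }
  logL0 <- obj(0)
  if (logL < logL0) { lambda <- 0; logL <- logL0 }
  pf <- profile_gls(x, lambda_transform(C, lambda))
  LR <- 2 * (logL - logL0)
  structure(list(lambda = lambda, sigma_sq = pf$sigma_sq, z0 = pf$mu,
                 logL = logL, logL0 = logL0, LR = LR,
                 p_value = pchisq(LR, df = 1, lower.tail = FALSE)),
            class = "signal_fit")
}

#' @export
print.signal_fit <- function(x, ...) {
  cat("Pagel's lambda\n")
  cat(sprintf("  lambda = %.4f   logL = %.4f   logL(0) = %.4f\n",
              x$lambda, x$logL, x$logL0))
  cat(sprintf("  LR = %.4f   p (chi^2, 1 df) = %.4g\n", x$LR, x$p_value))
  invisible(x)
}

#' Compare BM, OU and WN fits by Akaike weights
#'
#' Fits all three models to the same trait and tree and weights them by
#' `wAIC_m = exp(-0.5 * dAIC_m) / sum(exp(-0.5 * dAIC))`, where `dAIC` is
#' each model's AIC minus the minimum.
#'
#' @inheritParams fit_bm
#' @return A `model_comparison`: data frame with one row per model and
#'   columns `model`, `logL`, `k`, `AIC`, `dAIC`, `wAIC`; the individual
#'   fits are attached as attribute `fits`.
#' @export
compare_models <- function(x, tree) {
  fits <- list(BM = fit_bm(x, tree), OU = fit_ou(x, tree), WN = fit_wn(
    align_trait(x, default_tip_order(tree))))
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  daic <- aic - min(aic)
  w <- exp(-0.5 * daic)
  w <- w / sum(w)
  out <- data.frame(model = names(fits),
                    logL = vapply(fits, `[[`, numeric(1), "logL"),
                    k = vapply(fits, `[[`, integer(1), "k"),
                    AIC = aic, dAIC = daic, wAIC = w,
                    row.names = NULL)
  structure(out, fits = fits, class = c("model_comparison", "data.frame"))
}

#' Per-trait phylogenetic signal and model comparison report
#'
#' Runs [fit_lambda()] and [compare_models()] for every trait column of a
#' species trait table against a tree, reconciling the two by the
#' intersection of species labels (extra tips are pruned, extra table rows
#' dropped). Constant traits are skipped with a warning. Values are returned
#' at full precision; see [format_signal_report()] for the 2-decimal display
#' convention.
#'
#' @param table A `species_trait_table` (normally Ln(x+1)-transformed).
#' @param tree A `phylo` object.
#' @return A `signal_report` data frame: one row per fitted trait with
#'   columns `trait`, `wAIC_BM`, `wAIC_OU`, `wAIC_WN`, `lambda`, `p_value`,
#'   plus attribute `skipped` naming constant traits.
#' @export
signal_report <- function(table, tree) {
  if (!inherits(table, "species_trait_table"))
    stop("'table' must come from aggregate_species()", call. = FALSE)
  validate_tree(tree)
  sp <- intersect(table$species, tree$tip.label)
  if (length(sp) < 4)
    stop("fewer than 4 species shared between tree and trait table",
         call. = FALSE)
  tree <- prune_to(tree, sp)
  tab <- table[match(sp, table$species), , drop = FALSE]
  cols <- intersect(trait_names(), names(tab))
  rows <- list(); skipped <- character()
  for (cl in cols) {
    x <- stats::setNames(tab[[cl]], tab$species)
    if (stats::sd(x) == 0) { skipped <- c(skipped, cl); next }
    sig <- fit_lambda(x, tree)
    cmp <- compare_models(x, tree)
    w <- stats::setNames(cmp$wAIC, cmp$model)
    rows[[cl]] <- data.frame(trait = cl, wAIC_BM = w[["BM"]],
                             wAIC_OU = w[["OU"]], wAIC_WN = w[["WN"]],
                             lambda = sig$lambda, p_value = sig$p_value)
  }
  if (length(skipped))
    warning("constant trait(s) skipped: ", paste(skipped, collapse = ", "))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, skipped = skipped, n_species = length(sp),
            class = c("signal_report", "data.frame"))
}

#' Round a signal report for display
#'
#' Applies the 2-decimal display convention of comparative-analysis tables;
#' p-values below 0.01 print as `"<0.01"`.
#'
#' @param report A `signal_report`.
#' @return A data frame of formatted character/numeric columns.
#' @export
format_signal_report <- function(report) {
  data.frame(trait = report$trait,
             wAIC_BM = sprintf("%.2f", report$wAIC_BM),
             wAIC_OU = sprintf("%.2f", report$wAIC_OU),
             wAIC_WN = sprintf("%.2f", report$wAIC_WN),
             lambda = sprintf("%.2f", report$lambda),
             p_value = ifelse(report$p_value < 0.01, "<0.01",
                              sprintf("%.2f", report$p_value)),
             stringsAsFactors = FALSE)
}
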