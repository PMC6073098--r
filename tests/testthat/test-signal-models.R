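test_that("gaussian log-likelihood matches a dense independent evaluation", {
  # standard normal at its mode
  expect_equal(gaussian_loglik(0, 0, matrix(1)), -0.5 * log(2 * pi))
  for (seed in 1:5) {
    tr <- random_coal_tree(5, seed)
    V <- 0.7 * phylo_covariance(tr)
    set.seed(seed + 100)
    x <- rnorm(5)
    expect_equal(gaussian_loglik(x, 0.3, V),
                 naive_mvn_loglik(x, 0.3, V), tolerance = 1e-10)
  }
  V0 <- matrix(c(1, 1, 1, 1), 2)   # zero eigenvalue
  expect_error(gaussian_loglik(c(0, 0), 0, V0), "singular|positive definite")
})

test_that("white-noise fit has its closed form", {
  f <- fit_wn(c(0, 1, 2))
  expect_equal(f$z0, 1)
  expect_equal(f$sigma_sq, 2 / 3)
  expect_equal(f$logL, -1.5 * (log(2 * pi * 2 / 3) + 1))
  expect_equal(f$k, 2L)
  expect_equal(f$AIC, 4 - 2 * f$logL)
  # permutation invariance: no tree involved
  expect_equal(fit_wn(c(2, 0, 1))$logL, f$logL)
  expect_error(fit_wn(c(1, 1, 1)), "constant")
  expect_error(fit_wn(c(1, 2)), "at least 3")
})

test_that("Brownian fit solves the GLS normal equations", {
  # 2-tip equal-branch tree: hand-solvable GLS
  f2 <- fit_bm(c(A = 0, B = 2), read_newick("(A:1,B:1);"))
  expect_equal(f2$z0, 1)
  expect_equal(f2$sigma_sq, 1)
  # star tree: BM covariance is diagonal, so BM and WN coincide
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  x <- c(A = 0.3, B = -1, C = 2, D = 0.5)
  expect_equal(fit_bm(x, star)$logL, fit_wn(x)$logL, tolerance = 1e-12)
  expect_equal(fit_bm(x, star)$z0, mean(x))
})

test_that("every model's logL reproduces at its reported parameters", {
  for (seed in 1:6) {
    n <- sample(5:10, 1)
    tr <- random_coal_tree(n, seed + 40)
    x <- simulate_traits(tr, "BM", sigma_sq = 0.5, z0 = 2, seed = seed)[, 1]
    for (fit in list(fit_bm(x, tr), fit_ou(x, tr),
                     fit_wn(x[sort(names(x))]))) {
      V <- fit_covariance(fit, tr)
      ord <- sort(tr$tip.label)
      expect_equal(fit$logL, gaussian_loglik(x[ord], fit$z0, V),
                   tolerance = 1e-10, info = fit$model)
    }
    sig <- fit_lambda(x, tr)
    Vl <- sig$sigma_sq * lambda_transform(phylo_covariance(tr), sig$lambda)
    expect_equal(sig$logL, gaussian_loglik(x[sort(names(x))], sig$z0, Vl),
                 tolerance = 1e-10)
  }
})

test_that("OU nests BM at small alpha and WN at large alpha", {
  tr <- fixture_tree(n_tips = 12, n_clades = 3, seed = 6)
  x <- simulate_traits(tr, "BM", seed = 44)[, 1]
  ord <- sort(tr$tip.label)
  x <- x[ord]
  C <- phylo_covariance(tr, ord)
  D <- patristic_matrix(tr, ord)
  T_depth <- tree_depth(tr)
  logL_at <- function(a)
    leafevo:::profile_gls(x, leafevo:::ou_structure(C, D, a))$logL
  expect_equal(logL_at(1e-9 / T_depth), fit_bm(x, tr)$logL,
               tolerance = 1e-4)
  # the recently diverged sister pairs decorrelate last, so the white-noise
  # limit is probed well past the fit's own search bound
  expect_equal(logL_at(1e6 / T_depth), fit_wn(x)$logL, tolerance = 1e-4)
  R_big <- leafevo:::ou_structure(C, D, 1e6 / T_depth)
  Rcor <- R_big / sqrt(outer(diag(R_big), diag(R_big)))
  expect_lt(max(abs(Rcor[upper.tri(Rcor)])), 1e-6)
  # the fitted optimum can never fall below the Brownian limit
  f <- fit_ou(x, tr)
  expect_gte(f$logL, fit_bm(x, tr)$logL - 1e-6)
  expect_equal(f$k, 3L)
  expect_error(fit_ou(x, read_newick("((A:1,B:2):1,(C:1,D:1):1);")),
               "ultrametric")
})

test_that("OU pull strength is recoverable from simulated data", {
  tr <- fixture_tree(seed = 1)
  truth <- 2 / tree_depth(tr)
  X <- simulate_traits(tr, "OU", n_reps = 100, alpha = truth, seed = 77)
  a_hat <- apply(X, 2, function(x) fit_ou(x, tr)$alpha)
  expect_gt(median(a_hat), truth / 2)
  expect_lt(median(a_hat), truth * 2)
})

test_that("lambda profile fit hits boundaries, nests BM and WN", {
  tr <- fixture_tree(n_tips = 12, n_clades = 3, seed = 9)
  ord <- sort(tr$tip.label)
  C <- phylo_covariance(tr, ord)
  x <- simulate_traits(tr, "BM", seed = 55)[, 1][ord]
  # nesting identities: lambda = 1 is BM; lambda = 0 is WN on a chronogram
  pf1 <- leafevo:::profile_gls(x, lambda_transform(C, 1))
  expect_equal(pf1$logL, fit_bm(x, tr)$logL, tolerance = 1e-12)
  pf0 <- leafevo:::profile_gls(x, lambda_transform(C, 0))
  expect_equal(pf0$logL, fit_wn(x)$logL, tolerance = 1e-10)

  # boundary identity: lambda-hat = 0 forces LR = 0, p = 1
  w <- simulate_traits(tr, "WN", n_reps = 20, seed = 56)
  zero_seen <- FALSE
  for (i in seq_len(ncol(w))) {
    s <- fit_lambda(w[, i], tr)
    expect_gte(s$logL, s$logL0)
    if (s$lambda == 0) {
      zero_seen <- TRUE
      expect_equal(s$LR, 0)
      expect_equal(s$p_value, 1)
    }
  }
  expect_true(zero_seen)

  # optimality against a fine lambda grid
  tr27 <- fixture_tree(seed = 1)
  ord27 <- sort(tr27$tip.label)
  C27 <- phylo_covariance(tr27, ord27)
  X <- simulate_traits(tr27, "lambda", lambda = 0.5, n_reps = 5, seed = 57)
  for (i in 1:5) {
    xx <- X[, i][ord27]
    s <- fit_lambda(xx, tr27)
    grid_logL <- vapply(seq(0, 1, 0.05), function(l)
      leafevo:::profile_gls(xx, lambda_transform(C27, l))$logL, numeric(1))
    expect_gte(s$logL, max(grid_logL) - 1e-6)
    expect_true(s$lambda >= 0 && s$lambda <= 1)
  }
})

test_that("lambda estimates agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- fixture_tree(seed = 1)
  X <- simulate_traits(tr, "lambda", lambda = 0.6, n_reps = 3, seed = 21)
  for (i in 1:3) {
    ref <- phytools::phylosig(tr, X[, i], method = "lambda", test = TRUE)
    mine <- fit_lambda(X[, i], tr)
    expect_equal(mine$lambda, ref$lambda, tolerance = 1e-3)
    expect_equal(mine$logL, ref$logL, tolerance = 1e-6)
    expect_equal(mine$p_value, ref$P, tolerance = 1e-4)
  }
})

test_that("Akaike weights are normalized and shift-invariant", {
  tr <- fixture_tree(n_tips = 10, n_clades = 2, seed = 10)
  x <- simulate_traits(tr, "BM", seed = 58)[, 1]
  cmp <- compare_models(x, tr)
  expect_setequal(cmp$model, c("BM", "OU", "WN"))
  expect_equal(sum(cmp$wAIC), 1, tolerance = 1e-12)
  expect_equal(min(cmp$dAIC), 0)
  expect_equal(cmp$AIC, 2 * cmp$k - 2 * cmp$logL)
  # weights depend only on AIC differences
  shifted <- exp(-0.5 * ((cmp$AIC + 100) - min(cmp$AIC + 100)))
  expect_equal(cmp$wAIC, shifted / sum(shifted), tolerance = 1e-12)
  # equal AICs give uniform weights (the weight formula directly)
  w_eq <- exp(-0.5 * c(0, 0, 0)); w_eq <- w_eq / sum(w_eq)
  expect_equal(w_eq, rep(1 / 3, 3))
})

test_that("the per-trait report is deterministic and complete", {
  tr <- fixture_tree(seed = 1)
  m <- simulate_leaf_measurements(
    example_species_params(tr$tip.label, seed = 2), n_leaves = 12, seed = 3)
  tab <- ln1p_transform(aggregate_species(derive_traits(m), "mean"))
  rep1 <- signal_report(tab, tr)
  rep2 <- signal_report(tab, tr)
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1), 20L)
  expect_true(all(rep1$lambda >= 0 & rep1$lambda <= 1))
  expect_true(all(rep1$p_value > 0 & rep1$p_value <= 1))
  expect_equal(rep1$wAIC_BM + rep1$wAIC_OU + rep1$wAIC_WN,
               rep(1, 20), tolerance = 1e-9)
  # constant traits are skipped with a warning, not fitted
  tab2 <- tab
  tab2$A <- 1
  expect_warning(r2 <- signal_report(tab2, tr), "constant")
  expect_equal(nrow(r2), 19L)
  expect_equal(attr(r2, "skipped"), "A")
  # display formatting follows the 2-decimal convention
  disp <- format_signal_report(rep1)
  expect_true(all(grepl("^\\d\\.\\d{2}$", disp$wAIC_BM)))
  expect_true(all(disp$p_value == "<0.01" |
                    grepl("^\\d\\.\\d{2}$", disp$p_value)))
})
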