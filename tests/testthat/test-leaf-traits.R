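test_that("trait derivation matches closed-form geometry", {
  # unit circle, untoothed: the isoperimetric extremal case
  circ <- make_leaf(A = pi, P = 2 * pi, Pi = 2 * pi, removed = pi,
                    maj = 2, min = 2)
  tc <- derive_traits(circ)
  expect_equal(tc$ShapFact, 1)
  expect_equal(tc$Comp, 4 * pi)
  expect_equal(tc$FerDiam, 2)
  expect_equal(tc$FerDiamRatio, 1)
  expect_equal(tc$Pratio, 1)
  expect_equal(tc$TA, 0)
  expect_equal(tc$n_teeth, 0)
  expect_equal(tc$AvgTA, 0)

  # square of side 2
  sq <- make_leaf(A = 4, P = 8, Pi = 8, removed = 4, maj = 2 * sqrt(2),
                  min = 2)
  ts <- derive_traits(sq)
  expect_equal(ts$ShapFact, pi / 4)
  expect_equal(ts$Comp, 16)
  expect_equal(ts$FerDiam, 4 / sqrt(pi))

  # toothed toy: direct arithmetic
  ty <- make_leaf(A = 10, P = 16, Pi = 12, removed = 9, maj = 6, min = 3,
                  n1 = 8, n2 = 4)
  tt <- derive_traits(ty)
  expect_equal(tt$TA, 1)
  expect_equal(tt$TABA, 0.1)
  expect_equal(tt$TA_P, 0.0625)
  expect_equal(tt$TA_Pi, 1 / 12)
  expect_equal(tt$n_teeth, 12)
  expect_equal(tt$AvgTA, 0.125)
  expect_equal(tt$nteeth_P, 0.75)
  expect_equal(tt$nteeth_Pi, 1)
  expect_equal(tt$Pratio, 4 / 3)
})

test_that("derived traits obey scale covariance and shape bounds", {
  base <- make_leaf(A = 10, P = 16, Pi = 12, removed = 9, maj = 6, min = 3,
                    n1 = 8, n2 = 4)
  c_ <- 2.5
  scaled <- make_leaf(A = 10 * c_^2, P = 16 * c_, Pi = 12 * c_,
                      removed = 9 * c_^2, maj = 6 * c_, min = 3 * c_,
                      n1 = 8, n2 = 4)
  t0 <- derive_traits(base); t1 <- derive_traits(scaled)
  for (tr in c("ShapFact", "FerDiamRatio", "Pratio", "TABA", "Comp"))
    expect_equal(t1[[tr]], t0[[tr]], info = tr)
  for (tr in c("A", "TA"))
    expect_equal(t1[[tr]], t0[[tr]] * c_^2, info = tr)
  for (tr in c("P", "Pi", "MajLen", "MinLen", "FerDiam", "TA_P", "TA_Pi"))
    expect_equal(t1[[tr]], t0[[tr]] * c_, info = tr)

  # isoperimetric / isodiametric bounds on every generated record
  m <- simulate_leaf_measurements(
    example_species_params(paste0("sp", 1:10), seed = 3),
    n_leaves = 40, seed = 5)
  tm <- derive_traits(m)
  expect_true(all(tm$ShapFact <= 1 + 1e-12))
  expect_true(all(tm$ShapFact > 0))
  expect_true(all(tm$FerDiamRatio <= 1 + 1e-12))
  expect_equal(tm$ShapFact * tm$Comp, rep(4 * pi, nrow(tm)))
})

test_that("invalid measurements are rejected with the offending field", {
  bad_pi <- make_leaf(Pi = 20)          # Pi > P
  expect_gt(nrow(validate_measurements(bad_pi)), 0)
  expect_error(derive_traits(bad_pi), "internal_perimeter_cm")
  bad_axis <- make_leaf(maj = 2, min = 3)
  expect_error(derive_traits(bad_axis), "minor_axis_cm")
  bad_iso <- make_leaf(A = 100, P = 10, Pi = 10, removed = 100)  # ShapFact > 1
  expect_error(derive_traits(bad_iso), "isoperimetric")
  bad_teeth <- make_leaf(n1 = -1)
  expect_error(derive_traits(bad_teeth), "n_primary_teeth")
})

test_that("species aggregation takes the chosen statistic and orders", {
  leaves <- rbind(
    make_leaf(species = "a", leaf_id = "l1", A = pi, P = 2 * pi, Pi = 2 * pi,
              removed = pi, maj = 2, min = 2),
    make_leaf(species = "a", leaf_id = "l2", A = 4, P = 8, Pi = 8,
              removed = 4, maj = 2 * sqrt(2), min = 2),
    make_leaf(species = "b", leaf_id = "l1", A = 10, P = 16, Pi = 12,
              removed = 9, maj = 6, min = 3, n1 = 8, n2 = 4))
  tr <- derive_traits(leaves)
  m_mean <- aggregate_species(tr, "mean")
  m_min <- aggregate_species(tr, "min")
  m_max <- aggregate_species(tr, "max")
  expect_equal(m_mean$ShapFact[m_mean$species == "a"], (1 + pi / 4) / 2)
  expect_equal(m_min$ShapFact[m_min$species == "a"], pi / 4)
  expect_equal(m_max$ShapFact[m_max$species == "a"], 1)
  # single-leaf species: all three statistics coincide
  expect_equal(m_min[m_min$species == "b", trait_names()],
               m_max[m_max$species == "b", trait_names()],
               ignore_attr = TRUE)
  # element-wise ordering min <= mean <= max
  v <- trait_names()
  expect_true(all(as.matrix(m_min[v]) <= as.matrix(m_mean[v]) + 1e-12))
  expect_true(all(as.matrix(m_mean[v]) <= as.matrix(m_max[v]) + 1e-12))
})

test_that("Ln(x+1) transform is applied once and exactly", {
  leaves <- derive_traits(simulate_leaf_measurements(
    example_species_params(paste0("sp", 1:5), seed = 7), 10, seed = 8))
  tab <- aggregate_species(leaves, "mean")
  tr <- ln1p_transform(tab)
  expect_equal(attr(tr, "transform"), "ln1p")
  expect_equal(as.matrix(tr[trait_names()]),
               log1p(as.matrix(tab[trait_names()])))
  # closed-form anchors
  expect_equal(log1p(0), 0)
  expect_equal(log1p(exp(1) - 1), 1)
  expect_error(ln1p_transform(tr), "already")
})

test_that("trait correlations are Pearson to machine precision", {
  leaves <- derive_traits(simulate_leaf_measurements(
    example_species_params(paste0("sp", 1:8), seed = 9), 25, seed = 10))
  tab <- ln1p_transform(aggregate_species(leaves, "mean"))
  R <- trait_correlations(tab)
  expect_equal(dim(R), c(20L, 20L))
  expect_equal(R, t(R))
  expect_equal(diag(R), rep(1, 20), ignore_attr = TRUE)
  expect_true(all(abs(R[!is.na(R)]) <= 1 + 1e-12))
  # shape factor is 4*pi / compactness: necessarily negative correlation
  expect_lt(R["ShapFact", "Comp"], 0)
  # textbook covariance / sd formula, written out independently
  vals <- as.matrix(tab[trait_names()])
  n <- nrow(vals)
  for (pair in list(c("A", "P"), c("TA", "TABA"), c("ShapFact", "Comp"))) {
    x <- vals[, pair[1]]; y <- vals[, pair[2]]
    r_manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(R[pair[1], pair[2]], r_manual, tolerance = 1e-12)
  }
})

test_that("measurement CSV round-trips through the declared schema", {
  m <- simulate_leaf_measurements(
    example_species_params(c("x", "y"), seed = 1), 6, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_measurements(m, f, comment = "seed 2, demo")
  m2 <- read_measurements(f)
  expect_equal(m2$blade_area_cm2, m$blade_area_cm2, tolerance = 1e-12)
  expect_equal(nrow(m2), nrow(m))
  unlink(f)
})
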