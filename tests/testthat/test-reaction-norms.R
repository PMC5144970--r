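grid6 <- c(15, 20, 25, 30, 35, 40)

test_that("build_norm aggregates means and standard errors correctly", {
  tab <- one_genotype_table(setNames(rep(3, 6), grid6), n_rep = 5)
  nm <- build_norm(tab, "g1", "temperature")
  expect_equal(nm$mean_rates, rep(3, 6))
  expect_equal(nm$se_rates, rep(0, 6))
  # hand-computed SE for replicates {1, 2, 3}: sd/sqrt(n) = 1/sqrt(3)
  tab2 <- data.frame(genotype = "g1", mechanism = "x",
                     env_param = "temperature",
                     setting = rep(grid6, 3), replicate = rep(1:3, each = 6),
                     rate = rep(1:3, each = 6))
  nm2 <- build_norm(tab2, "g1", "temperature")
  expect_equal(nm2$mean_rates, rep(2, 6))
  expect_equal(nm2$se_rates, rep(1 / sqrt(3), 6), tolerance = 1e-12)
})

test_that("a fully-missing setting degrades the norm with a warning", {
  tab <- one_genotype_table(setNames(rep(3, 6), grid6), n_rep = 2)
  tab$rate[tab$setting == 25] <- NA
  expect_warning(nm <- build_norm(tab, "g1", "temperature"), "25")
  expect_equal(length(nm$settings), 5)
  tab$rate[tab$setting %in% c(15, 20)] <- NA
  expect_error(suppressWarnings(build_norm(tab, "g1", "temperature")), "g1")
})

test_that("df = 2 reproduces a straight line exactly", {
  tab <- one_genotype_table(setNames(1 + 0.2 * grid6, grid6))
  fit <- fit_natural_spline(build_norm(tab, "g1", "temperature"), df = 2)
  expect_equal(predict(fit, grid6), 1 + 0.2 * grid6, tolerance = 1e-8)
})

test_that("the spline fit equals a direct basis-matrix least-squares solve", {
  # noisy replicate-level data from a quadratic
  tab <- one_genotype_table(setNames(-(grid6 - 33)^2 / 50 + 10, grid6),
                            n_rep = 5, sd = 0.3, seed = 21)
  nm <- build_norm(tab, "g1", "temperature")
  fit <- fit_natural_spline(nm, df = 5)
  # independent oracle: build the same natural-spline basis and solve the
  # normal equations directly
  interior <- stats::quantile(grid6, c(1, 2, 3) / 4, type = 7, names = FALSE)
  B <- cbind(1, splines::ns(nm$data$setting, knots = interior,
                            Boundary.knots = range(grid6)))
  beta <- solve(crossprod(B), crossprod(B, nm$data$rate))
  Bg <- cbind(1, splines::ns(grid6, knots = interior,
                             Boundary.knots = range(grid6)))
  expect_equal(predict(fit, grid6), drop(Bg %*% beta), tolerance = 1e-8)
})

test_that("df equal to the number of settings interpolates the means", {
  mu <- -(grid6 - 33)^2 / 50 + 10
  tab <- one_genotype_table(setNames(mu, grid6), n_rep = 3)
  fit <- fit_natural_spline(build_norm(tab, "g1", "temperature"), df = 6)
  expect_equal(predict(fit, grid6), mu, tolerance = 1e-8)
})

test_that("duplicated replicates give the same fit as weighted data", {
  tab <- one_genotype_table(setNames(-(grid6 - 30)^2 / 40 + 8, grid6),
                            n_rep = 1, sd = 0.2, seed = 5)
  tab2 <- rbind(tab, tab)  # every observation twice
  f1 <- fit_natural_spline(build_norm(tab, "g1", "temperature"), df = 4)
  f2 <- fit_natural_spline(build_norm(tab2, "g1", "temperature"), df = 4)
  expect_equal(predict(f1, grid6), predict(f2, grid6), tolerance = 1e-10)
})

test_that("df outside the identifiable range is rejected", {
  tab <- one_genotype_table(setNames(rep(3, 6), grid6))
  nm <- build_norm(tab, "g1", "temperature")
  expect_error(fit_natural_spline(nm, df = 7), "exceeds")
  expect_error(fit_natural_spline(nm, df = 1), "df")
})

test_that("no extrapolation outside the observed setting range", {
  tab <- one_genotype_table(setNames(rep(3, 6), grid6))
  fit <- fit_natural_spline(build_norm(tab, "g1", "temperature"))
  expect_error(predict(fit, 41), "extrapolation")
  expect_error(predict(fit, 14.9), "extrapolation")
})

test_that("optima are found by grid search and never leave the range", {
  # quadratic with analytic argmax 33.0
  tab <- one_genotype_table(setNames(-(grid6 - 33)^2 / 40 + 10, grid6))
  fit <- fit_natural_spline(build_norm(tab, "g1", "temperature"), df = 6)
  opt <- estimate_optimum(fit, grid_step = 0.1)
  expect_lt(abs(opt$optimum_setting - 33), 0.1 + 1e-9)
  expect_false(opt$at_boundary)

  # monotone-decreasing salt norm: optimum at 0 M, at the boundary
  salt <- c(0, 0.2, 0.4, 0.8, 1.2, 1.6)
  tabs <- one_genotype_table(setNames(3.29 - 1.8 * salt, salt),
                             env_param = "salt")
  opts <- estimate_optimum(fit_natural_spline(build_norm(tabs, "g1", "salt")))
  expect_equal(opts$optimum_setting, 0)
  expect_true(opts$at_boundary)

  # symmetric peak centred between grid points
  tabp <- one_genotype_table(setNames(-(grid6 - 27.5)^2 / 30 + 5, grid6))
  optp <- estimate_optimum(fit_natural_spline(build_norm(tabp, "g1",
                                                         "temperature"),
                                              df = 6), grid_step = 0.05)
  expect_lt(abs(optp$optimum_setting - 27.5), 0.05 + 1e-9)

  # property: optimum always inside the data range
  for (seed in 1:20) {
    t2 <- one_genotype_table(setNames(rnorm(6, 3, 1), grid6), n_rep = 2,
                             sd = 0.3, seed = seed)
    t2$rate <- pmax(0, t2$rate)
    o <- estimate_optimum(fit_natural_spline(build_norm(t2, "g1",
                                                        "temperature")))
    expect_gte(o$optimum_setting, 15)
    expect_lte(o$optimum_setting, 40)
  }
})

test_that("sucrose norms are fitted on a log axis and return original units", {
  suc <- c(0.015, 0.15, 1.5, 5, 15, 30)
  mu <- 3.45 - 0.28 * (log10(suc) - 0.7)^2
  tab <- one_genotype_table(setNames(mu, suc), env_param = "sucrose")
  opt <- estimate_optimum(fit_natural_spline(build_norm(tab, "g1", "sucrose"),
                                             df = 6))
  expect_gt(opt$optimum_setting, 0.015)
  expect_lt(opt$optimum_setting, 30)
  expect_lt(abs(log10(opt$optimum_setting) - 0.7), 0.1)
})

test_that("elevation and shape decomposition is exact arithmetic", {
  mk_norm <- function(vals) {
    tab <- one_genotype_table(setNames(vals, seq_along(vals) * 10),
                              n_rep = 1)
    build_norm(tab, "g1", "temperature", min_settings = 3)
  }
  ctrl <- mk_norm(c(1, 2, 3))
  # pure elevation change
  up <- mk_norm(c(1.5, 2.5, 3.5))
  es <- elevation_and_shape(up, ctrl)
  expect_equal(es$elevation_diff, 0.5)
  expect_equal(unname(es$shape_profile), c(0, 0, 0))
  # pure shape change: reversed norm
  rev <- mk_norm(c(3, 2, 1))
  es2 <- elevation_and_shape(rev, ctrl)
  expect_equal(es2$elevation_diff, 0)
  expect_equal(unname(es2$shape_profile), c(2, 0, -2))
  # shape profile sums to zero for arbitrary norms (machine precision)
  for (seed in 1:10) {
    set.seed(seed)
    a <- mk_norm(runif(3, 0, 4)); b <- mk_norm(runif(3, 0, 4))
    expect_lt(abs(sum(elevation_and_shape(a, b)$shape_profile)), 1e-12)
  }
  expect_error(elevation_and_shape(mk_norm(1:3), mk_norm(1:4)), "grids")
})

test_that("known optimum shifts are recovered at the stated replication", {
  ctrl <- spline_peak_norm(33.7)
  mut <- spline_peak_norm(25.3, height = 3.5)
  expect_equal(ctrl$peak, 33.7, tolerance = 1e-3)
  expect_equal(mut$peak, 25.3, tolerance = 1e-3)
  tol <- 25 / 1000 + 0.5
  hits <- vapply(1:30, function(seed) {
    tc <- one_genotype_table(setNames(ctrl$mean_rates, grid6), n_rep = 5,
                             sd = 0.2, seed = 100 + seed)
    tm <- one_genotype_table(setNames(mut$mean_rates, grid6), n_rep = 5,
                             sd = 0.2, seed = 200 + seed)
    oc <- estimate_optimum(fit_natural_spline(build_norm(tc, "g1",
                                                         "temperature")))
    om <- estimate_optimum(fit_natural_spline(build_norm(tm, "g1",
                                                         "temperature")))
    c(abs(oc$optimum_setting - 33.7) <= tol,
      abs(om$optimum_setting - 25.3) <= tol)
  }, logical(2))
  expect_gte(mean(hits), 0.8)
})
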