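# Synthetic-scenario generator: determinism, proportion control, designed q.

test_that("gaussian field: white-noise Moran, determinism, autocorrelation", {
  g0 <- generate_gaussian_field(c(20, 20), 0, seed = 2)
  expect_equal(mean(g0), 0, tolerance = 1e-12)
  expect_equal(mean(g0^2), 1, tolerance = 1e-9)

  # white noise: lag-1 Moran's I near E[I] (3 SD via the analytic z)
  u <- tessellate(landuse_grid(matrix(1L, 20, 20)), 1)
  W <- build_weights(u, "rook")
  r <- morans_i(as.vector(t(g0)), W)
  expect_lt(abs(r$z), 3)

  expect_identical(generate_gaussian_field(c(15, 17), 4, seed = 9),
                   generate_gaussian_field(c(15, 17), 4, seed = 9))
  expect_false(identical(generate_gaussian_field(c(15, 17), 4, seed = 9),
                         generate_gaussian_field(c(15, 17), 4, seed = 10)))

  g10 <- generate_gaussian_field(c(100, 100), 10, seed = 5)
  u100 <- tessellate(landuse_grid(matrix(1L, 100, 100)), 1)
  W100 <- build_weights(u100, "queen")
  expect_gt(morans_i(as.vector(t(g10)), W100)$I, 0.5)

  expect_error(generate_gaussian_field(c(0, 5), 1), "positive")
  expect_error(generate_gaussian_field(c(5, 5), -1), ">= 0")
})

test_that("land-use series: proportion control and transitions", {
  fp <- list(shape = c(200, 200), correlation_range = 6)
  # degenerate single-class target with identity transitions
  lu1 <- generate_landuse_series(list(shape = c(10, 10)),
                                 class_targets = c(forestland = 1),
                                 transition_matrix = diag(6), T = 3, seed = 1)
  for (g in lu1) expect_true(all(g$values == 2L))

  lu2 <- generate_landuse_series(fp, c(farmland = 0.5, water = 0.5),
                                 diag(6), T = 1, seed = 2)
  p <- tabulate(lu2[[1]]$values, 6) / 4e4
  expect_true(p[1] >= 0.48 && p[1] <= 0.52)
  expect_true(p[4] >= 0.48 && p[4] <= 0.52)

  # construction share increases monotonically under farmland -> construction
  P <- diag(6); P[1, 1] <- 0.9; P[1, 5] <- 0.1
  lu3 <- generate_landuse_series(fp, c(farmland = 0.6, construction = 0.1,
                                       forestland = 0.3), P, T = 4, seed = 3)
  shares <- vapply(lu3, function(g) mean(g$values == 5L), 0)
  expect_true(all(diff(shares) > 0))

  expect_error(generate_landuse_series(fp, c(farmland = 0.6, water = 0.5)),
               "sum to 1")

  # default targets realised within +-2% on a 200x200 grid
  lu4 <- generate_landuse_series(fp, T = 1, seed = 8)
  p4 <- tabulate(lu4[[1]]$values, 6) / 4e4
  expect_true(all(abs(p4 - default_class_targets()) <= 0.02))
})

test_that("drivers: designed q recovered exactly via factor_q", {
  sc <- small_scenario()
  lus <- sc$landuse_series
  dq <- c(X1 = 0, X5 = 1, X8 = 0.6)
  drv <- generate_drivers(lus, dq, seed = 12)
  q <- vapply(names(dq), function(id)
    factor_q(as.vector(drv$drivers[[id]]$values),
             as.vector(drv$strata[[id]]))$q, 0)
  expect_equal(q[["X1"]], 0, tolerance = 1e-12)
  expect_equal(q[["X5"]], 1, tolerance = 1e-12)
  expect_equal(q[["X8"]], 0.6, tolerance = 1e-9)

  expect_error(generate_drivers(lus, c(X1 = 1.2)), "\\[0, 1\\]")
  expect_error(generate_drivers(lus, c(Z9 = 0.5)), "X1..X9")

  # X9 strata track construction density: construction share differs across
  # strata of the generating field
  drv9 <- generate_drivers(lus, c(X9 = 0.5), seed = 12)
  constr <- lus[[length(lus)]]$values == 5L
  by_stratum <- tapply(as.vector(constr), as.vector(drv9$strata$X9), mean)
  expect_gt(max(by_stratum) - min(by_stratum), 0.05)
})

test_that("counties: partition, connectivity, determinism", {
  lab1 <- generate_counties(c(20, 20), 1, seed = 3)
  expect_true(all(lab1 == 1L))

  lab <- generate_counties(c(200, 200), 64, seed = 3)
  expect_equal(sort(unique(as.vector(lab))), 1:64)
  expect_true(all(tabulate(lab, 64) > 0))
  expect_identical(lab, generate_counties(c(200, 200), 64, seed = 3))

  # each county is a connected region (8-conn check on a smaller case)
  lab2 <- generate_counties(c(40, 40), 10, seed = 6)
  for (k in 1:10) {
    mask <- matrix(NA_integer_, 40, 40)
    mask[lab2 == k] <- 1L
    ps <- label_patches(mask, connectivity = 4L)
    expect_equal(nrow(ps), 1L, info = paste("county", k))
  }
  expect_error(generate_counties(c(3, 3), 10), "between 1")
})

test_that("scenario bundle invariants and determinism", {
  sc <- small_scenario()
  expect_length(sc$landuse_series, 5L)
  expect_length(sc$ndvi_series, 5L)
  shape <- dim(sc$landuse_series[[1]]$values)
  for (g in c(sc$landuse_series, sc$ndvi_series, sc$drivers))
    expect_identical(dim(g$values), shape)
  expect_identical(dim(sc$county_labels), shape)
  for (g in sc$ndvi_series)
    expect_true(all(g$values >= -1 & g$values <= 1))
  expect_true(all(rowSums(sc$truth$class_proportions_per_time) > 0.999))
  expect_equal(rowSums(sc$truth$transition_matrix), rep(1, 6),
               ignore_attr = TRUE)

  sc2 <- generate_scenario(shape = c(60L, 60L), n_counties = 12L, seed = 4L)
  expect_identical(sc2$ndvi_series[[3]]$values, sc$ndvi_series[[3]]$values)
  expect_identical(sc2$county_labels, sc$county_labels)
})

test_that("scenario writes a readable raster bundle", {
  dir <- withr::local_tempdir()
  sc <- small_scenario()
  write_scenario(sc, dir)
  lu <- read_raster(file.path(dir, "landuse_t1.asc"), "landuse")
  expect_identical(lu$values, sc$landuse_series[[1]]$values)
  nd <- read_raster(file.path(dir, "ndvi_t5.asc"), "continuous")
  expect_identical(nd$values, sc$ndvi_series[[5]]$values)
  expect_true(file.exists(file.path(dir, "scenario_manifest.json")))
  expect_true(file.exists(file.path(dir, "truth_designed_q.csv")))
})
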