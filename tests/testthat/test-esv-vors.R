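# ESV / CESI and the VORS composite indices.

test_that("compute_esv arithmetic and missing-unit flagging", {
  a <- matrix(0, 3, 6)
  a[1, 2] <- 10                       # pure forest unit, area 10
  a[2, c(1, 4)] <- c(4.5, 4.5)        # farmland + water
  vc <- c(farmland = 2, forestland = 5, grassland = 0, water = 6,
          construction = 0, bareland = 0)
  r <- compute_esv(a, vc)
  expect_equal(r$ESV[1], 50)
  expect_equal(r$AESV[1], 5)
  expect_equal(r$ESV[2], 36)
  expect_equal(r$AESV[2], 4)
  expect_true(r$missing[3])           # zero total area

  z <- compute_esv(a[1:2, ], rep(0, 6))
  expect_equal(z$ESV, c(0, 0))
  expect_equal(z$AESV, c(0, 0))
})

test_that("CESI is an affine map, clipped, and VC-scale invariant", {
  expect_equal(compute_cesi(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(compute_cesi(c(-5, 10), domain_values = c(0, 8)), c(0, 1))
  expect_error(compute_cesi(rep(3, 4)), "degenerate")

  set.seed(5)
  areas <- matrix(runif(60), 10, 6)
  vc <- runif(6)
  c1 <- compute_cesi(compute_esv(areas, vc)$AESV)
  c2 <- compute_cesi(compute_esv(areas, 7.3 * vc)$AESV)
  expect_equal(c1, c2, tolerance = 1e-12)
  # strict order preservation
  aesv <- compute_esv(areas, vc)$AESV
  expect_equal(order(aesv), order(compute_cesi(aesv)))
})

test_that("minmax_normalize contract", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(2, 4, 6), invert = TRUE), c(1, 0.5, 0))
  x <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(x), x)    # idempotent on [0,1]-spanning input
  expect_error(minmax_normalize(rep(1, 3)), "degenerate")
})

test_that("compute_er weighted coefficients", {
  sh <- rbind(c(0, 1, 0, 0, 0, 0),
              c(0.5, 0, 0, 0.5, 0, 0))
  co <- default_resilience_coefficients()
  co["forestland", ] <- c(0.9, 0.8)
  expect_equal(compute_er(sh, co)[1], 0.4 * 0.9 + 0.6 * 0.8)
  co2 <- co; co2[, ] <- 1
  expect_equal(compute_er(sh, co2), c(1, 1))
  co3 <- co
  co3["farmland", ] <- c(0.4, 0.5); co3["water", ] <- c(0.7, 0.8)
  expect_equal(compute_er(sh, co3)[2], 0.4 * 0.55 + 0.6 * 0.65)
  expect_error(compute_er(sh[, 1:5]), "6 class")
})

test_that("PH and HI composites with bounds and monotonicity", {
  expect_equal(compute_ph(1, 1, 1), 1)
  expect_equal(compute_ph(0, 0.5, 0.9), 0)
  expect_equal(compute_ph(0.512, 1, 1), 0.8)
  expect_equal(compute_hi(1, 1), 1)
  expect_equal(compute_hi(0, 0.7), 0)
  expect_equal(compute_hi(0.49, 1), 0.7)
  expect_error(compute_ph(-0.1, 0.5, 0.5), "non-negative")

  set.seed(11)
  for (i in 1:50) {
    tr <- runif(3)
    ph <- compute_ph(tr[1], tr[2], tr[3])
    expect_gte(ph, min(tr) - 1e-12)
    expect_lte(ph, max(tr) + 1e-12)
    hi <- compute_hi(ph, runif(1))
    expect_true(hi >= 0 && hi <= 1)
  }
  # HI monotone in both arguments
  expect_gte(compute_hi(0.6, 0.5), compute_hi(0.4, 0.5))
  expect_gte(compute_hi(0.6, 0.5), compute_hi(0.6, 0.3))
})

test_that("compute_eo uses the published weight decomposition", {
  w <- default_eo_weights()
  expect_equal(sum(w), 1)
  expect_equal(unname(w["SHDI"] + w["AWMPFD"]), 0.35)      # LH
  expect_equal(unname(w["FI1"] + w["CONT"]), 0.35)         # LC
  expect_equal(unname(w["FI2"] + w["COHESION1"] + w["FI3"] + w["COHESION2"]),
               0.30)                                       # IPC
  ones <- as.data.frame(as.list(setNames(rep(1, 8), names(w))))
  zeros <- as.data.frame(as.list(setNames(rep(0, 8), names(w))))
  expect_equal(compute_eo(ones)$EO, 1)
  expect_equal(compute_eo(zeros)$EO, 0)
  expect_error(compute_eo(ones[, 1:7]), "missing metric")
})

test_that("compute_ev normalises unit mean NDVI", {
  v <- matrix(0.2, 4, 4); v[, 3:4] <- 0.8
  nd <- continuous_grid(v)
  u <- tessellate(nd, 2)
  ev <- compute_ev(nd, u)
  expect_equal(sort(unique(ev$EV)), c(0, 1))
  expect_error(compute_ev(continuous_grid(matrix(0.5, 4, 4)), u), "degenerate")
  v3 <- cbind(matrix(0.2, 2, 2), matrix(0.5, 2, 2), matrix(0.8, 2, 2))
  nd3 <- continuous_grid(v3)
  u3 <- tessellate(nd3, 2)
  expect_equal(compute_ev(nd3, u3)$EV, c(0, 0.5, 1))
  expect_error(compute_ev(continuous_grid(matrix(1.5, 4, 4)), u), "\\[-1, 1\\]")
})

test_that("Fisher-Jenks matches the exhaustive oracle on all small cases", {
  # deterministic gap case
  b <- jenks_breaks(c(1, 2, 10, 11), 2)
  expect_equal(classify(c(1, 2, 10, 11), b), c(1L, 1L, 2L, 2L))
  # k = number of distinct values: singleton classes
  b4 <- jenks_breaks(c(3, 9, 27, 81), 4)
  expect_equal(classify(c(3, 9, 27, 81), b4), 1:4)
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
  expect_error(jenks_breaks(1:10, 1), ">= 2")

  for (s in 1:15) {
    set.seed(200 + s)
    n <- sample(5:12, 1)
    k <- sample(2:4, 1)
    x <- round(runif(n, 0, 100), 1)
    if (length(unique(x)) < k) next
    o <- oracle_jenks_assign(unique(x), k)
    b <- jenks_breaks(unique(x), k)
    got <- classify(o$sorted, b)
    expect_equal(got, o$assign, info = sprintf("seed %d n %d k %d", s, n, k))
    expect_equal(b$wss, o$wss, tolerance = 1e-9)
  }
})

test_that("quantile pre-binned jenks stays close to exact on large input", {
  set.seed(31)
  x <- c(rnorm(3000, 0), rnorm(3000, 6))
  exact <- jenks_breaks(x, 2, max_bins = 10000L)  # exact (6000 distinct)
  binned <- jenks_breaks(x, 2, max_bins = 512L)
  wss_of <- function(b) {
    cl <- classify(x, b)
    sum(tapply(x, cl, function(v) sum((v - mean(v))^2)))
  }
  expect_lt(wss_of(binned) / wss_of(exact), 1.01)
})

test_that("published fixed HI breaks classify boundary probes correctly", {
  br <- reference_hi_breaks()
  labs <- level_labels()
  expect_equal(labs[classify(0.30, br)], "moderate")
  expect_equal(labs[classify(c(0.10, 0.174, 0.1741, 0.254, 0.324, 0.4,
                               0.493, 0.4931, 1.0), br)],
               c("low", "low", "relatively low", "relatively low", "moderate",
                 "fairly good", "fairly good", "excellent", "excellent"))
})
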