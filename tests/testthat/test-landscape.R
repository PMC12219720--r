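# Landscape metrics against analytic cases and the brute-force oracle.

test_that("label_patches: squares, checkerboards, connectivity semantics", {
  ps <- label_patches(matrix(2L, 3, 3))
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$area, 9L)
  expect_equal(ps$perimeter, 12)

  chk <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  ps4 <- label_patches(chk, connectivity = 4L)
  expect_equal(nrow(ps4), 4L)
  expect_true(all(ps4$area == 1L))
  expect_true(all(ps4$perimeter == 4))

  diagm <- matrix(c(1L, 2L, 2L, 1L), 2, 2)  # same-class cells touch diagonally
  expect_equal(nrow(label_patches(diagm, 8L)), 2L)
  expect_equal(nrow(label_patches(diagm, 4L)), 4L)

  expect_error(label_patches(matrix(NA_integer_, 2, 2)), "empty")
})

test_that("shdi analytic values and bounds", {
  expect_equal(shdi(c(0, 1, 0, 0, 0, 0)), 0)
  expect_equal(shdi(c(0.5, 0.5)), log(2))
  expect_equal(shdi(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  for (s in 1:10) {
    set.seed(s)
    p <- runif(6); p <- p / sum(p)
    expect_gte(shdi(p), 0)
    expect_lte(shdi(p), log(6) + 1e-12)
  }
})

test_that("awmpfd: square exactness, single-cell guard, rectangle", {
  sq <- label_patches(matrix(1L, 5, 5))
  expect_equal(awmpfd(sq, 25), 1)

  singles <- label_patches(matrix(c(1L, 2L, 2L, 1L), 2, 2), connectivity = 4L)
  expect_equal(awmpfd(singles, 4), 1)

  rect <- matrix(2L, 2, 4)
  ps <- label_patches(rect)
  expect_equal(awmpfd(ps, 8), 2 * log(3) / log(8), tolerance = 1e-12)
  expect_equal(awmpfd(ps, 8), 1.0566, tolerance = 1e-4)
})

test_that("contagion: conventions and analytic checkerboard value", {
  expect_equal(contagion(matrix(3L, 4, 4)), 100)

  # 2-class checkerboard: P'_12 = P'_21 = 1/2 exactly, so
  # CONTAG = 100 (1 + log(1/2)/log(4)) = 50 at any size
  chk <- outer(1:6, 1:6, function(r, c) 1L + (r + c) %% 2L)
  expect_equal(contagion(chk), 50, tolerance = 1e-12)
  # maximally interspersed 2-class stripes (equal like/unlike adjacency mix)
  # instead reach the formula's minimum of 0
  stripes <- matrix(rep_len(c(1L, 2L), 36), 6, 6)
  expect_equal(contagion(stripes), 0, tolerance = 1e-12)

  half <- cbind(matrix(1L, 4, 2), matrix(2L, 4, 2))
  expect_equal(contagion(half), oracle_contagion(half), tolerance = 1e-12)

  expect_error(contagion(matrix(1L, 1, 1)), "2 valid cells")
})

test_that("fragmentation index and cohesion basics", {
  one <- label_patches(matrix(4L, 3, 3))
  expect_equal(fragmentation_index(one, 9), 1 / 9)
  expect_equal(fragmentation_index(one[0, ], 9), 0)   # no patches
  expect_error(fragmentation_index(one, 0), "positive")

  chk <- outer(1:6, 1:6, function(r, c) 1L + (r + c) %% 2L)
  ps <- label_patches(chk, connectivity = 4L)
  expect_equal(nrow(ps), 36L)
  expect_equal(fragmentation_index(ps, 36), 1)

  # full-window single patch: formula maximum
  full <- label_patches(matrix(4L, 10, 10))
  expect_equal(cohesion(full, 100),
               (1 - 40 / (40 * 10)) / (1 - 1 / 10) * 100)
  # absent class convention
  expect_equal(cohesion(full[full$class == 2L, ], 100), 0)
  expect_error(cohesion(full, 1), "Z >= 2")

  # scattered singles less cohesive than one compact patch of equal area
  compact <- matrix(1L, 6, 6); compact[2:3, 2:3] <- 4L
  spread <- matrix(1L, 6, 6)
  spread[cbind(c(1, 1, 6, 6), c(1, 6, 1, 6))] <- 4L
  c1 <- cohesion({p <- label_patches(compact); p[p$class == 4L, ]}, 36)
  c2 <- cohesion({p <- label_patches(spread); p[p$class == 4L, ]}, 36)
  expect_gt(c1, c2)
})

test_that("oracle equivalence on random small windows (2-3 classes)", {
  for (s in 1:12) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    w <- random_window(nr, nc, classes = 1:sample(2:3, 1), seed = 100 + s)
    for (conn in c(4L, 8L)) {
      got <- label_patches(w, conn)
      exp <- oracle_patches(w, conn)
      expect_equal(nrow(got), nrow(exp), info = sprintf("seed %d conn %d", s, conn))
      # compare patch multisets (class, area, perimeter)
      key <- function(d) sort(sprintf("%d/%d/%g", d$class, d$area, d$perimeter))
      expect_equal(key(got), key(exp))
    }
    expect_equal(contagion(w), oracle_contagion(w), tolerance = 1e-12)
    p <- tabulate(w, 6) / length(w)
    expect_equal(shdi(p), oracle_shdi(w), tolerance = 1e-12)
    expect_equal(awmpfd(label_patches(w), length(w)), oracle_awmpfd(w),
                 tolerance = 1e-12)
    ps <- label_patches(w)
    expect_equal(cohesion(ps[ps$class == 2L, ], length(w)),
                 oracle_cohesion(w, 2L), tolerance = 1e-12)
  }
})

test_that("unit_metrics agrees with per-window metrics and respects walls", {
  set.seed(77)
  v <- matrix(sample(1:4, 144, TRUE), 12, 12)
  g <- landuse_grid(v)
  u <- tessellate(g, 3)
  m <- unit_metrics(g, u)
  for (uid in c(1L, 6L, 16L)) {
    rr <- ((u$unit_index$row[uid] - 1) * 3 + 1):(u$unit_index$row[uid] * 3)
    cc <- ((u$unit_index$col[uid] - 1) * 3 + 1):(u$unit_index$col[uid] * 3)
    win <- v[rr, cc]
    ps <- label_patches(win)
    expect_equal(m$SHDI[uid], shdi(tabulate(win, 6) / 9), tolerance = 1e-12)
    expect_equal(m$AWMPFD[uid], awmpfd(ps, 9), tolerance = 1e-12)
    expect_equal(m$FI1[uid], fragmentation_index(ps, 9), tolerance = 1e-12)
    expect_equal(m$CONT[uid], contagion(win), tolerance = 1e-12)
    expect_equal(m$COHESION1[uid],
                 cohesion(ps[ps$class == 4L, ], 9), tolerance = 1e-12)
  }
  # bounds over all units
  expect_true(all(m$SHDI >= 0 & m$SHDI <= log(6) + 1e-12))
  expect_true(all(m$CONT >= -1e-9 & m$CONT <= 100 + 1e-9))
  expect_true(all(m$COHESION1 >= -1e-9 & m$COHESION1 <= 100 + 1e-9))
  expect_true(all(m$FI1 >= 0))
})

test_that("splitting a patch never decreases FI1", {
  v <- matrix(1L, 3, 3); v[, 2] <- 1L
  g <- landuse_grid(v)
  u <- tessellate(g, 3)
  fi_before <- unit_metrics(g, u)$FI1
  v2 <- v; v2[2, ] <- 2L   # cut the block in two (4-conn sense)
  fi_after <- unit_metrics(landuse_grid(v2), u, connectivity = 4L)$FI1
  expect_gte(fi_after, fi_before)
})
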