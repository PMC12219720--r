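# Level-change typing and control-zone assignment.

test_that("change typing: published predicates and the gap rule", {
  expect_equal(as.character(classify_change_type(c(3, 3, 3, 3, 3))$type),
               "stable")
  expect_equal(as.character(classify_change_type(c(5, 4, 4, 3, 2))$type),
               "continuous decline")
  r <- classify_change_type(c(2, 4, 3, 3, 5))
  expect_equal(as.character(r$type), "fluctuating rise")
  expect_equal(r$S_L, 3)
  g <- classify_change_type(c(2, 3, 2, 2, 2))
  expect_equal(as.character(g$type), "stable")
  expect_true(g$fluctuating_neutral)
  expect_equal(as.character(classify_change_type(c(1, 1, 2))$type),
               "continuous rise")
  expect_equal(as.character(classify_change_type(c(4, 5, 1, 2, 3))$type),
               "fluctuating decline")
  expect_error(classify_change_type(c(3)), "2 timepoints")
  expect_error(classify_change_type(c(3, 6)), "1-5")
})

test_that("typing is exhaustive and exclusive over all 3125 trajectories", {
  traj <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5, 1:5))
  res <- classify_change_types(traj)
  expect_equal(nrow(res), 5L^5L)
  expect_false(anyNA(res$type))
  expect_equal(sort(unique(as.character(res$type))),
               sort(c("continuous decline", "fluctuating decline", "stable",
                      "fluctuating rise", "continuous rise")))
  # S_L consistency: S_L = L_T - L_1
  expect_equal(res$S_L, traj[, 5] - traj[, 1])
})

test_that("reversal symmetry maps declines to rises and fixes stable", {
  pair <- c("continuous decline" = "continuous rise",
            "fluctuating decline" = "fluctuating rise",
            "stable" = "stable",
            "fluctuating rise" = "fluctuating decline",
            "continuous rise" = "continuous decline")
  set.seed(15)
  for (i in 1:200) {
    tr <- sample(1:5, 5, TRUE)
    fwd <- as.character(classify_change_type(tr)$type)
    bwd <- as.character(classify_change_type(rev(tr))$type)
    expect_equal(bwd, unname(pair[fwd]), info = paste(tr, collapse = ","))
  }
})

test_that("zone lookup: 23 entries, no overlap, fallbacks complete the 25", {
  lk <- default_zone_lookup()
  expect_equal(nrow(lk), 23L)
  expect_equal(anyDuplicated(paste(lk$level_class, lk$type_class)), 0L)
  all_pairs <- expand.grid(level_class = c("Ia", "IIa", "IIIa", "IVa", "Va"),
                           type_class = c("Ib", "IIb", "IIIb", "IVb", "Vb"),
                           stringsAsFactors = FALSE)
  za <- assign_control_zone(all_pairs$level_class, all_pairs$type_class)
  expect_equal(nrow(za), 25L)
  expect_false(anyNA(za$zone))
  expect_equal(sum(za$fallback), 2L)
  fb <- za[za$fallback, ]
  expect_setequal(paste(fb$level_class, fb$type_class), c("Ia Vb", "Va Ib"))
})

test_that("published zone assignments", {
  expect_equal(as.character(assign_control_zone("Va", "Vb")$zone),
               "emergency control")
  expect_equal(as.character(assign_control_zone("IIIa", "IVb")$zone),
               "dynamic regulation")
  expect_equal(as.character(assign_control_zone("Ia", "Ib")$zone),
               "sensitive monitoring")
  expect_equal(as.character(assign_control_zone("IVa", "IIIb")$zone),
               "strict control")
  expect_equal(as.character(assign_control_zone("IIa", "IVb")$zone),
               "preventive management")
  bad <- default_zone_lookup()
  bad$zone[1] <- "no such zone"
  expect_error(assign_control_zone("Va", "Vb", bad), "malformed")
  dup <- rbind(default_zone_lookup(), default_zone_lookup()[1, ])
  expect_error(assign_control_zone("Va", "Vb", dup), "overlapping")
})

test_that("class codings: level Ia = best health, type Ib = continuous rise", {
  expect_equal(as.character(level_to_class(5)), "Ia")
  expect_equal(as.character(level_to_class(1)), "Va")
  expect_equal(as.character(change_type_to_class("continuous rise")), "Ib")
  expect_equal(as.character(change_type_to_class("continuous decline")), "Vb")
  expect_equal(as.character(change_type_to_class("stable")), "IIIb")
})

test_that("county_level_class: ordering and degenerate input", {
  vals <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  counties <- 1:5
  r <- county_level_class(vals, counties)
  expect_equal(as.character(r$level_class), c("Ia", "IIa", "IIIa", "IVa", "Va"))
  # monotonicity property: higher score never gets a worse class
  set.seed(33)
  for (i in 1:5) {
    v <- runif(8)
    cty <- 1:8
    rr <- county_level_class(v, cty)
    o <- order(rr$score, decreasing = TRUE)
    expect_true(all(diff(rr$level[o]) <= 0))
  }
  expect_error(county_level_class(0.5, 1), "natural breaks")
  # area weighting
  r2 <- county_level_class(c(1, 0), c(1, 1), weights = c(3, 1),
                           score_breaks = fixed_breaks(c(0.2, 0.4, 0.6, 0.8)))
  expect_equal(r2$score, 0.75)
})
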