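# Synthetic-scenario generator with known ground truth.
#
# The generator emulates the study's input stack at desk scale: a 200 x 200
# lattice of 1 km cells (3 km assessment units), five land-cover timepoints
# with urban-expansion style transitions, NDVI tied to cover class, nine
# driver surfaces with exactly designed stratified-variance structure, and a
# 64-county partition. Every component is a pure function of (params, seed).

#' Spatially autocorrelated Gaussian random field
#'
#' White noise smoothed by FFT convolution with a Gaussian kernel of standard
#' deviation `correlation_range` cells (padded, so no wrap-around
#' correlation), then standardised to zero mean and unit population variance.
#' `correlation_range = 0` returns standardised white noise.
#'
#' @param shape integer length-2 grid dimensions (rows, cols).
#' @param correlation_range kernel SD in cells (>= 0).
#' @param seed integer seed; identical seed and params give identical output.
#' @return numeric matrix.
#' @export
generate_gaussian_field <- function(shape, correlation_range = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) stop("shape must be 2 positive integers")
  if (correlation_range < 0) stop("correlation_range must be >= 0")
  nr <- shape[1L]; nc <- shape[2L]
  if (correlation_range == 0) {
    z <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  } else {
    pad <- as.integer(ceiling(3 * correlation_range))
    pr <- nr + 2L * pad; pc <- nc + 2L * pad
    noise <- with_seed(seed, matrix(stats::rnorm(pr * pc), pr, pc))
    # Gaussian kernel in FFT (wrapped) layout
    dr <- pmin(0:(pr - 1L), pr - 0:(pr - 1L))
    dc <- pmin(0:(pc - 1L), pc - 0:(pc - 1L))
    kern <- exp(-outer(dr^2, dc^2, "+") / (2 * correlation_range^2))
    sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
      (pr * pc)
    z <- sm[pad + seq_len(nr), pad + seq_len(nc)]
  }
  (z - mean(z)) / sqrt(pop_var(z))
}

#' Default land-cover class proportions
#'
#' A forest/farmland-dominated landscape with a large water body, echoing a
#' lake-plain urban agglomeration: farmland 0.32, forest 0.38, grassland
#' 0.08, water 0.12, construction 0.07, bare 0.03.
#' @return named numeric vector summing to 1.
#' @export
default_class_targets <- function() {
  c(farmland = 0.32, forestland = 0.38, grassland = 0.08,
    water = 0.12, construction = 0.07, bareland = 0.03)
}

#' Default per-step class transition matrix
#'
#' Mild urban expansion: farmland and grassland convert to construction at
#' 2% / step and farmland to water at 0.5% (wetland dynamics); other classes
#' essentially persistent. Rows sum to 1.
#' @return 6 x 6 row-stochastic matrix.
#' @export
default_transition_matrix <- function() {
  P <- diag(6)
  P[1, 5] <- 0.02; P[1, 4] <- 0.005; P[1, 1] <- 1 - 0.025
  P[3, 5] <- 0.02; P[3, 3] <- 0.98
  P[6, 3] <- 0.01; P[6, 6] <- 0.99
  dimnames(P) <- list(names(LANDUSE_CLASSES), names(LANDUSE_CLASSES))
  P
}

#' Generate a land-use time series
#'
#' Timepoint 1 thresholds a latent Gaussian field at the target-proportion
#' quantiles (classes assigned in code order along the sorted field), so
#' realised proportions match the targets to within one cell. Later
#' timepoints apply `transition_matrix` with spatially clustered
#' destinations: a cell leaves its class with the row's off-diagonal mass and
#' moves to class d with probability proportional to
#' `P[c, d] * (eps + neighbourhood density of d)`, so e.g. construction grows
#' around existing construction.
#'
#' @param field_params list with `shape`, `correlation_range` (cells,
#'   default 8), `cell_size` (km, default 1), `origin`.
#' @param class_targets named proportions over the six classes, summing to 1
#'   (tolerance 1e-9).
#' @param transition_matrix 6 x 6 row-stochastic matrix.
#' @param T number of timepoints (>= 1).
#' @param seed integer seed.
#' @param eps baseline destination weight (default 0.1) allowing spontaneous
#'   conversion away from existing patches.
#' @return list of `landuse_grid`, length T.
#' @export
generate_landuse_series <- function(field_params, class_targets = default_class_targets(),
                                    transition_matrix = default_transition_matrix(),
                                    T = 5L, seed = 1L, eps = 0.1) {
  if (abs(sum(class_targets) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (T < 1L) stop("T must be >= 1")
  if (!identical(dim(transition_matrix), c(6L, 6L)) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9))
    stop("transition matrix must be 6 x 6 with rows summing to 1")
  shape <- field_params$shape
  rng <- if (is.null(field_params$correlation_range)) 8 else field_params$correlation_range
  cell <- if (is.null(field_params$cell_size)) 1 else field_params$cell_size
  origin <- if (is.null(field_params$origin)) c(0, 0) else field_params$origin
  targets <- numeric(N_CLASSES)
  nm <- names(class_targets)
  if (is.null(nm)) targets[seq_along(class_targets)] <- class_targets
  else {
    if (!all(nm %in% names(LANDUSE_CLASSES))) stop("unknown class name in targets")
    targets[LANDUSE_CLASSES[nm]] <- class_targets
  }
  g <- generate_gaussian_field(shape, rng, sub_seed(seed, 1L))
  n <- length(g)
  counts <- diff(round(cumsum(c(0, targets)) * n))
  cls <- integer(n)
  cls[order(g)] <- rep.int(seq_len(N_CLASSES), counts)
  cur <- matrix(cls, shape[1L], shape[2L])
  out <- vector("list", T)
  out[[1L]] <- landuse_grid(cur, cell_size = cell, origin = origin)
  if (T > 1L) {
    for (t in 2L:T) {
      cur <- transition_step(cur, transition_matrix, eps,
                             sub_seed(seed, 100L + t))
      out[[t]] <- landuse_grid(cur, cell_size = cell, origin = origin)
    }
  }
  out
}

# One spatially clustered transition step.
transition_step <- function(cur, P, eps, seed) {
  nr <- nrow(cur); nc <- ncol(cur)
  n <- nr * nc
  # 8-neighbour density of each class
  dens <- vector("list", N_CLASSES)
  for (k in seq_len(N_CLASSES)) dens[[k]] <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    nb <- cur[r1 + dr, c1 + dc, drop = FALSE]
    for (k in seq_len(N_CLASSES))
      dens[[k]][r1, c1] <- dens[[k]][r1, c1] + (!is.na(nb) & nb == k) / 8
  }
  with_seed(seed, {
    leave_p <- 1 - diag(P)[cur]
    u <- stats::runif(n)
    leaving <- which(u < leave_p & !is.na(cur))
    for (i in leaving) {
      cls <- cur[i]
      w <- P[cls, ] * (eps + vapply(dens, function(d) d[i], 0))
      w[cls] <- 0
      if (sum(w) > 0) cur[i] <- sample.int(N_CLASSES, 1L, prob = w)
    }
    cur
  })
}

#' Default NDVI class means
#'
#' Deliberately compressed into `[0.05, 0.55]` so that the planted-hotspot
#' boost (3 background SDs of unit-mean NDVI) cannot clip at the NDVI ceiling
#' of 1.
#' @return named numeric vector per class.
#' @export
default_ndvi_means <- function() {
  c(farmland = 0.35, forestland = 0.55, grassland = 0.45,
    water = 0.05, construction = 0.10, bareland = 0.15)
}

#' NDVI raster tied to land cover
#'
#' Class mean + smooth noise, clipped to `[-1, 1]`.
#'
#' @param landuse a `landuse_grid`.
#' @param seed integer seed.
#' @param class_means per-class NDVI means.
#' @param noise_sd SD of the smooth noise field (default 0.08).
#' @param noise_range correlation range of the noise (cells).
#' @return a `continuous_grid`.
#' @export
generate_ndvi <- function(landuse, seed, class_means = default_ndvi_means(),
                          noise_sd = 0.08, noise_range = 5) {
  base <- matrix(class_means[landuse$values], nrow(landuse$values))
  noise <- generate_gaussian_field(dim(landuse$values), noise_range, seed)
  v <- base + noise_sd * noise
  v <- pmin(pmax(v, -1), 1)
  v[is.na(landuse$values)] <- NA
  dim(v) <- dim(landuse$values)
  continuous_grid(v, cell_size = landuse$cell_size, origin = landuse$origin)
}

DRIVER_IDS <- paste0("X", 1:9)
DRIVER_NAMES <- c(X1 = "annual precipitation", X2 = "annual mean temperature",
                  X3 = "net primary productivity", X4 = "elevation",
                  X5 = "slope", X6 = "nighttime light index",
                  X7 = "per-capita farmland", X8 = "population density",
                  X9 = "land urbanisation degree")

#' Default designed q values for the nine drivers
#'
#' Fraction of each driver's variance explained by its own generating strata;
#' socio-economic drivers (X6, X8, X9) get the strongest stratified
#' structure, mirroring the qualitative ordering of driver importance in
#' lake-plain urban agglomerations.
#' @return named numeric vector over X1..X9, values in `[0, 1]`.
#' @export
default_designed_q <- function() {
  c(X1 = 0.20, X2 = 0.30, X3 = 0.25, X4 = 0.50, X5 = 0.45,
    X6 = 0.60, X7 = 0.20, X8 = 0.70, X9 = 0.65)
}

#' Generate the nine driver surfaces with exact stratified structure
#'
#' Each driver is (stratum-mean surface) + within-stratum noise, with the
#' noise rescaled post hoc so that the Geodetector q of the driver against
#' its own generating strata equals `designed_q[id]` exactly (not in
#' expectation). Drivers X8 and X9 take their strata from quantile bins of
#' smoothed construction-land density at the last timepoint, so they co-vary
#' with urbanisation; the rest use independent smooth fields. Each surface is
#' affinely mapped to a plausible physical range (q is affine-invariant).
#'
#' @param landuse_series list of `landuse_grid`.
#' @param designed_q named vector over a subset of X1..X9, values in `[0,1]`.
#' @param seed integer seed.
#' @param n_strata strata count per driver (default 5).
#' @return list with `drivers` (named list of `continuous_grid`) and
#'   `strata` (named list of integer matrices, the generating strata).
#' @export
generate_drivers <- function(landuse_series, designed_q = default_designed_q(),
                             seed = 1L, n_strata = 5L) {
  if (!all(names(designed_q) %in% DRIVER_IDS))
    stop("designed_q keys must be among X1..X9")
  if (any(designed_q < 0 | designed_q > 1))
    stop("designed_q values must lie in [0, 1]")
  last <- landuse_series[[length(landuse_series)]]
  shape <- dim(last$values)
  ranges <- list(X1 = c(1200, 2000), X2 = c(14, 20), X3 = c(300, 1200),
                 X4 = c(5, 1800), X5 = c(0, 35), X6 = c(0, 60),
                 X7 = c(0.01, 0.2), X8 = c(10, 4000), X9 = c(0, 90))
  constr_dens <- smooth_density(last$values == LANDUSE_CLASSES[["construction"]], 6)
  drivers <- list(); strata <- list()
  for (i in seq_along(designed_q)) {
    id <- names(designed_q)[i]
    k <- match(id, DRIVER_IDS)
    base <- if (id %in% c("X8", "X9")) constr_dens
    else generate_gaussian_field(shape, 10, sub_seed(seed, 200L + k))
    # quantile strata of the generating field
    qs <- stats::quantile(base, probs = seq(0, 1, length.out = n_strata + 1L),
                          names = FALSE, type = 7L)
    st <- findInterval(base, qs[-c(1L, n_strata + 1L)], left.open = TRUE) + 1L
    st <- matrix(as.integer(st), shape[1L], shape[2L])
    noise <- generate_gaussian_field(shape, 2, sub_seed(seed, 300L + k))
    y <- stratified_surface(st, designed_q[[i]], noise)
    rg <- ranges[[id]]
    yr <- range(y)
    v <- if (yr[2L] > yr[1L]) rg[1L] + (y - yr[1L]) / (yr[2L] - yr[1L]) * (rg[2L] - rg[1L])
    else matrix(mean(rg), shape[1L], shape[2L])
    drivers[[id]] <- continuous_grid(v, cell_size = last$cell_size,
                                     origin = last$origin)
    strata[[id]] <- st
  }
  list(drivers = drivers, strata = strata)
}

# Exact-q surface: between-strata component + rescaled within component.
stratified_surface <- function(strata, q, noise) {
  sv <- as.vector(strata)
  nv <- as.vector(noise)
  f <- factor(sv)
  grp_mean <- as.vector(tapply(nv, f, mean))[as.integer(f)]
  w <- nv - grp_mean                      # pure within-stratum variation
  s <- as.integer(f) - mean(as.integer(f))    # increasing stratum means, centred
  if (q <= 0) {
    y <- w
  } else if (q >= 1) {
    y <- s
  } else {
    ssb <- sum((s - mean(s))^2)
    ssw <- sum(w^2)
    cc <- sqrt(ssb * (1 - q) / (q * ssw))
    y <- s + cc * w
  }
  matrix(y, nrow(strata), ncol(strata))
}

# Mean of a logical matrix over a square moving window of half-width r
# (box smoothing via cumulative sums; cheap and deterministic).
smooth_density <- function(mask, r) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(apply(m, 2L, cumsum), 1L, cumsum)  # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, nr + 1L, nc + 1L)
  pad[-1L, -1L] <- cs
  r1 <- as.vector(pmax(row(m) - r, 1L)); r2 <- as.vector(pmin(row(m) + r, nr))
  c1 <- as.vector(pmax(col(m) - r, 1L)); c2 <- as.vector(pmin(col(m) + r, nc))
  tot <- pad[cbind(r2 + 1L, c2 + 1L)] - pad[cbind(r1, c2 + 1L)] -
    pad[cbind(r2 + 1L, c1)] + pad[cbind(r1, c1)]
  area <- (r2 - r1 + 1) * (c2 - c1 + 1)
  matrix(tot / area, nr, nc)
}

#' County partition by multi-source breadth-first growth
#'
#' `n_counties` seed cells are drawn uniformly; counties then grow outward
#' one ring per round (4-neighbourhood, deterministic scan order), i.e.
#' Voronoi under the geodesic lattice metric. Every county is non-empty and
#' connected by construction, and every cell is labelled.
#'
#' @param shape grid dimensions (rows, cols).
#' @param n_counties number of counties (1 <= n <= cells).
#' @param seed integer seed.
#' @return integer label matrix with labels 1..n_counties.
#' @export
generate_counties <- function(shape, n_counties, seed = 1L) {
  shape <- as.integer(shape)
  n <- prod(shape)
  if (n_counties < 1L || n_counties > n)
    stop("n_counties must be between 1 and the number of cells")
  nr <- shape[1L]; nc <- shape[2L]
  lab <- matrix(0L, nr, nc)
  seeds <- with_seed(seed, sample.int(n, n_counties))
  lab[seeds] <- seq_len(n_counties)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  while (any(lab == 0L)) {
    grew <- FALSE
    for (s in shifts) {
      dr <- s[1L]; dc <- s[2L]
      r1 <- max(1L, 1L - dr):min(nr, nr - dr)
      c1 <- max(1L, 1L - dc):min(nc, nc - dc)
      src <- lab[r1 + dr, c1 + dc, drop = FALSE]
      dstv <- lab[r1, c1, drop = FALSE]
      fill <- dstv == 0L & src != 0L
      if (any(fill)) {
        dstv[fill] <- src[fill]
        lab[r1, c1] <- dstv
        grew <- TRUE
      }
    }
    if (!grew) break  # unreachable cells (cannot happen on a full lattice)
  }
  lab
}

#' Generate a complete synthetic scenario
#'
#' Bundles land use over T timepoints, NDVI per timepoint (with an optional
#' planted hotspot block of assessment units whose NDVI is raised by
#' `hotspot_contrast` background SDs of the unit-mean NDVI), the nine driver
#' surfaces, a county partition, and the ground truth needed to verify every
#' downstream stage.
#'
#' @param shape grid dims (default c(200, 200) cells).
#' @param cell_size cell edge km (default 1).
#' @param unit_km assessment-unit edge km (default 3).
#' @param T timepoints (default 5, mirroring 2005/2010/2015/2020/2022).
#' @param n_counties counties (default 64).
#' @param class_targets,transition_matrix,designed_q see the component
#'   generators.
#' @param hotspot logical: plant a hotspot block (default TRUE).
#' @param hotspot_units edge length of the hotspot block in units (default 8).
#' @param hotspot_contrast boost in background SDs of unit-mean NDVI
#'   (default 3).
#' @param correlation_range latent-field range in cells (default 8).
#' @param seed master seed.
#' @return a `synthetic_scenario` list: landuse_series, ndvi_series, drivers,
#'   driver_strata, county_labels, units, years, truth.
#' @export
generate_scenario <- function(shape = c(200L, 200L), cell_size = 1, unit_km = 3,
                              T = 5L, n_counties = 64L,
                              class_targets = default_class_targets(),
                              transition_matrix = default_transition_matrix(),
                              designed_q = default_designed_q(),
                              hotspot = TRUE, hotspot_units = 8L,
                              hotspot_contrast = 3,
                              correlation_range = 8, seed = 1L) {
  fp <- list(shape = shape, correlation_range = correlation_range,
             cell_size = cell_size, origin = c(0, 0))
  lus <- generate_landuse_series(fp, class_targets, transition_matrix, T,
                                 sub_seed(seed, 11L))
  units <- tessellate(lus[[1L]], unit_km)
  ndvi <- lapply(seq_len(T), function(t)
    generate_ndvi(lus[[t]], sub_seed(seed, 20L + t)))
  hot_units <- logical(nrow(units$unit_index))
  if (isTRUE(hotspot)) {
    b <- as.integer(hotspot_units)
    ur <- units$n_unit_rows; uc <- units$n_unit_cols
    pos <- with_seed(sub_seed(seed, 40L), c(sample.int(max(1L, ur - b), 1L),
                                            sample.int(max(1L, uc - b), 1L)))
    sel_r <- pos[1L]:(pos[1L] + b - 1L)
    sel_c <- pos[2L]:(pos[2L] + b - 1L)
    hot_ids <- as.vector(outer((sel_r - 1L) * uc, sel_c, "+"))
    hot_units[hot_ids] <- TRUE
    cell_mask <- matrix(hot_units[units$unit_id], nrow(units$unit_id))
    for (t in seq_len(T)) {
      um <- zonal_stat(ndvi[[t]], units, "mean")$value
      bg_sd <- stats::sd(um[!hot_units], na.rm = TRUE)
      v <- ndvi[[t]]$values
      v[cell_mask] <- pmin(v[cell_mask] + hotspot_contrast * bg_sd, 1)
      ndvi[[t]] <- continuous_grid(v, cell_size = cell_size, origin = c(0, 0))
    }
  }
  drv <- generate_drivers(lus, designed_q, sub_seed(seed, 30L))
  counties <- generate_counties(shape, n_counties, sub_seed(seed, 50L))
  props <- t(vapply(lus, function(g)
    tabulate(g$values, nbins = N_CLASSES) / sum(!is.na(g$values)),
    numeric(N_CLASSES)))
  colnames(props) <- names(LANDUSE_CLASSES)
  truth <- list(class_proportions_per_time = props,
                planted_hotspot_mask = hot_units,
                hotspot_contrast = if (isTRUE(hotspot)) hotspot_contrast else NA,
                designed_q = designed_q,
                transition_matrix = transition_matrix)
  structure(list(landuse_series = lus, ndvi_series = ndvi,
                 drivers = drv$drivers, driver_strata = drv$strata,
                 county_labels = counties, units = units,
                 years = seq_len(T), truth = truth, seed = seed),
            class = "synthetic_scenario")
}

#' Write a scenario to disk (ASCII rasters + manifest + truth tables)
#'
#' @param scenario a `synthetic_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(scenario$landuse_series)) {
    write_raster(scenario$landuse_series[[t]],
                 file.path(dir, sprintf("landuse_t%d.asc", t)))
    write_raster(scenario$ndvi_series[[t]],
                 file.path(dir, sprintf("ndvi_t%d.asc", t)))
  }
  for (id in names(scenario$drivers))
    write_raster(scenario$drivers[[id]], file.path(dir, paste0(id, ".asc")))
  cg <- scenario$landuse_series[[1L]]
  write_raster(continuous_grid(scenario$county_labels,
                               cell_size = cg$cell_size, origin = cg$origin),
               file.path(dir, "counties.asc"))
  data.table::fwrite(
    data.frame(time = seq_len(nrow(scenario$truth$class_proportions_per_time)),
               scenario$truth$class_proportions_per_time),
    file.path(dir, "truth_class_proportions.csv"))
  data.table::fwrite(data.frame(driver = names(scenario$truth$designed_q),
                                designed_q = unname(scenario$truth$designed_q)),
                     file.path(dir, "truth_designed_q.csv"))
  jsonlite::write_json(list(T = length(scenario$landuse_series),
                            seed = scenario$seed,
                            shape = dim(scenario$landuse_series[[1L]]$values),
                            unit_km = scenario$units$unit_km,
                            drivers = names(scenario$drivers)),
                       file.path(dir, "scenario_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
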