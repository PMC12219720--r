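# Tessellation into assessment units and zonal aggregation.

#' Tessellate a raster into square assessment units
#'
#' Units are axis-aligned `unit_km` x `unit_km` blocks anchored at the raster
#' origin (matrix row 1 / column 1). Edge blocks may be partial and are kept,
#' flagged by their cell counts in the unit index. Unit ids are assigned in
#' row-major order over the unit lattice.
#'
#' @param grid an `eco_grid` providing shape and cell size.
#' @param unit_km unit edge length in km; must be a positive integer multiple
#'   of the grid cell size.
#' @return an `assessment_grid`: list with `unit_id` (integer matrix mapping
#'   cells to units), `unit_km`, `n_unit_rows`, `n_unit_cols`, and
#'   `unit_index` (data.frame unit_id, row, col, cell_count, area_km2);
#'   `cell_count` counts valid (non-nodata) cells.
#' @export
tessellate <- function(grid, unit_km) {
  stopifnot(inherits(grid, "eco_grid"))
  b <- unit_km / grid$cell_size
  if (!isTRUE(all.equal(b, round(b))) || b < 1)
    stop("unit_km must be a positive integer multiple of cell_size")
  b <- as.integer(round(b))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  n_ur <- as.integer(ceiling(nr / b)); n_uc <- as.integer(ceiling(nc / b))
  urow <- (seq_len(nr) - 1L) %/% b + 1L
  ucol <- (seq_len(nc) - 1L) %/% b + 1L
  unit_id <- matrix(0L, nr, nc)
  unit_id[] <- (urow[row(unit_id)] - 1L) * n_uc + ucol[col(unit_id)]
  valid <- !is.na(grid$values)
  counts <- integer(n_ur * n_uc)
  tb <- tabulate(unit_id[valid], nbins = n_ur * n_uc)
  counts[seq_along(tb)] <- tb
  ids <- seq_len(n_ur * n_uc)
  idx <- data.frame(
    unit_id = ids,
    row = (ids - 1L) %/% n_uc + 1L,
    col = (ids - 1L) %% n_uc + 1L,
    cell_count = counts,
    area_km2 = counts * grid$cell_size^2
  )
  structure(list(unit_id = unit_id, unit_km = unit_km,
                 cell_size = grid$cell_size,
                 n_unit_rows = n_ur, n_unit_cols = n_uc, unit_index = idx),
            class = "assessment_grid")
}

#' @export
print.assessment_grid <- function(x, ...) {
  cat(sprintf("<assessment_grid> %d x %d units of %g km (%d units, %d partial)\n",
              x$n_unit_rows, x$n_unit_cols, x$unit_km, nrow(x$unit_index),
              sum(x$unit_index$cell_count <
                  max(x$unit_index$cell_count, na.rm = TRUE))))
  invisible(x)
}

# Normalise a zones argument to an integer label matrix plus zone count.
zone_matrix <- function(zones) {
  if (inherits(zones, "assessment_grid"))
    list(m = zones$unit_id, n = nrow(zones$unit_index))
  else {
    m <- as.matrix(zones)
    storage.mode(m) <- "integer"
    list(m = m, n = max(m, na.rm = TRUE))
  }
}

#' Zonal statistics of a continuous grid
#'
#' NA cells of the value grid are excluded. Zones with no valid cell get
#' `NA` and `missing = TRUE`. The `majority` statistic (for integer-coded
#' grids) breaks ties toward the lowest code.
#'
#' @param grid a `continuous_grid` or `landuse_grid`.
#' @param zones an `assessment_grid` or an integer label matrix of the same
#'   shape.
#' @param stat one of "mean", "sum", "majority".
#' @return data.frame with columns zone, value, missing.
#' @export
zonal_stat <- function(grid, zones, stat = c("mean", "sum", "majority")) {
  stat <- match.arg(stat)
  z <- zone_matrix(zones)
  v <- grid$values
  if (!identical(dim(v), dim(z$m))) stop("grid and zones shapes differ")
  keep <- !is.na(v) & !is.na(z$m)
  zid <- z$m[keep]
  x <- as.double(v[keep])
  out <- rep(NA_real_, z$n)
  if (stat %in% c("mean", "sum")) {
    s <- rowsum(x, zid)
    ids <- as.integer(rownames(s))
    if (stat == "mean") {
      n <- rowsum(rep(1, length(zid)), zid)
      out[ids] <- s[, 1L] / n[, 1L]
    } else out[ids] <- s[, 1L]
  } else {
    codes <- as.integer(x)
    ncode <- max(codes)
    cnt <- tabulate((zid - 1L) * ncode + codes, nbins = z$n * ncode)
    cm <- matrix(cnt, nrow = z$n, ncol = ncode, byrow = TRUE)
    has <- rowSums(cm) > 0
    # which.max returns the first (lowest-code) maximum: documented tie-break
    out[has] <- apply(cm[has, , drop = FALSE], 1L, which.max)
  }
  data.frame(zone = seq_len(z$n), value = out, missing = is.na(out))
}

#' Per-zone land-cover composition (area shares of the six classes)
#'
#' @param landuse a `landuse_grid`.
#' @param zones an `assessment_grid` or integer label matrix.
#' @return matrix (zones x 6) of shares summing to 1 per zone with valid
#'   cells; rows of all-NA for zones without valid cells.
#' @export
class_proportions <- function(landuse, zones) {
  stopifnot(inherits(landuse, "landuse_grid"))
  z <- zone_matrix(zones)
  v <- landuse$values
  if (!identical(dim(v), dim(z$m))) stop("landuse and zones shapes differ")
  keep <- !is.na(v) & !is.na(z$m)
  zid <- z$m[keep]
  cls <- v[keep]
  cnt <- tabulate((zid - 1L) * N_CLASSES + cls, nbins = z$n * N_CLASSES)
  cm <- matrix(cnt, nrow = z$n, ncol = N_CLASSES, byrow = TRUE)
  tot <- rowSums(cm)
  shares <- cm / ifelse(tot > 0, tot, NA_real_)
  colnames(shares) <- names(LANDUSE_CLASSES)
  shares
}
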