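# Raster containers and ESRI ASCII grid I/O.
#
# Grids are plain S3 lists around a numeric/integer matrix. Row 1 / column 1 of
# the matrix is the raster origin; matrices are row-major in the geographic
# sense (row = northing band). Missing cells are NA in memory; the `nodata`
# sentinel only appears in files.

LANDUSE_CLASSES <- c(farmland = 1L, forestland = 2L, grassland = 3L,
                     water = 4L, construction = 5L, bareland = 6L)
N_CLASSES <- 6L

#' Continuous-valued raster grid
#'
#' @param values numeric matrix; NA marks missing cells.
#' @param cell_size cell edge length in km (> 0).
#' @param origin numeric length-2 lower-left corner coordinate (x, y).
#' @param nodata sentinel written to / read from files for missing cells.
#' @return an object of class `continuous_grid`.
#' @export
continuous_grid <- function(values, cell_size = 1, origin = c(0, 0),
                            nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (any(!is.finite(values) & !is.na(values)))
    stop("continuous grid values must be finite or NA")
  structure(list(values = values, cell_size = cell_size,
                 origin = as.numeric(origin), nodata = nodata),
            class = c("continuous_grid", "eco_grid"))
}

#' Categorical land-use raster grid
#'
#' Codes 1..6 are farmland, forestland, grassland, water, construction land
#' and bare land, in that fixed order.
#'
#' @inheritParams continuous_grid
#' @return an object of class `landuse_grid`.
#' @export
landuse_grid <- function(values, cell_size = 1, origin = c(0, 0),
                         nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  ok <- is.na(values) | (values >= 1L & values <= N_CLASSES)
  if (!all(ok))
    stop("land-use codes must be in 1..6 (or NA for nodata)")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(list(values = values, cell_size = cell_size,
                 origin = as.numeric(origin), nodata = nodata),
            class = c("landuse_grid", "eco_grid"))
}

#' @export
print.eco_grid <- function(x, ...) {
  cat(sprintf("<%s> %d x %d cells, cell %g km, origin (%g, %g), %d nodata\n",
              class(x)[1L], nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1L], x$origin[2L], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.eco_grid <- function(x) dim(x$values)

#' Check that a set of grids share shape and georeference
#'
#' All rasters entering one analysis run must be aligned; no resampling is
#' performed.
#'
#' @param ... grids (`eco_grid` objects).
#' @return invisibly TRUE; errors on mismatch.
#' @export
check_grid_stack <- function(...) {
  gs <- list(...)
  if (length(gs) < 2L) return(invisible(TRUE))
  ref <- gs[[1L]]
  for (g in gs[-1L]) {
    if (!identical(dim(g$values), dim(ref$values)))
      stop("shape mismatch in raster stack: ", paste(dim(g$values), collapse = "x"),
           " vs ", paste(dim(ref$values), collapse = "x"))
    if (!isTRUE(all.equal(g$cell_size, ref$cell_size)) ||
        !isTRUE(all.equal(g$origin, ref$origin)))
      stop("georeference mismatch in raster stack")
  }
  invisible(TRUE)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Values are written at full double precision (`%.17g`) so that a write/read
#' round trip is exact.
#'
#' @param grid an `eco_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "eco_grid"))
  v <- grid$values
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.17g", grid$origin[1L]),
           sprintf("yllcorner %.17g", grid$origin[2L]),
           sprintf("cellsize %.17g", grid$cell_size),
           sprintf("NODATA_value %.17g", as.double(grid$nodata)))
  out <- v
  out[is.na(out)] <- grid$nodata
  body <- if (is.integer(v)) {
    apply(out, 1L, function(r) paste(format(r, scientific = FALSE), collapse = " "))
  } else {
    apply(out, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file path.
#' @param type "continuous", "landuse", or "auto" (landuse if all values are
#'   integers in 1..6).
#' @return a `continuous_grid` or `landuse_grid`.
#' @export
read_raster <- function(path, type = c("auto", "continuous", "landuse")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  dat <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(dat) != nr * nc)
    stop("ASCII grid body has ", length(dat), " values, expected ", nr * nc)
  m <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  is_lu <- all(is.na(m) | (m == round(m) & m >= 1 & m <= N_CLASSES))
  if (type == "landuse" || (type == "auto" && is_lu)) {
    if (!is_lu) stop("raster is not a valid land-use grid: ", path)
    landuse_grid(m, cell_size = vals[["cellsize"]],
                 origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
                 nodata = nodata)
  } else {
    continuous_grid(m, cell_size = vals[["cellsize"]],
                    origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
                    nodata = nodata)
  }
}
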