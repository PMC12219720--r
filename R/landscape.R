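# Landscape metrics per assessment unit (FRAGSTATS definitions).
#
# Metrics are computed per unit window in isolation: patch connectivity and
# cell adjacencies never cross unit borders, matching per-unit partition
# statistics. The implementation labels all windows simultaneously with
# vectorised min-label propagation; a unit border acts exactly like a window
# boundary.

# ---- connected components -------------------------------------------------

# Label connected components of equal-class cells, confined to regions.
# cls: integer matrix (NA = nodata); region: integer matrix (NA allowed).
# Returns an integer matrix of patch labels (1..P, NA outside valid cells).
label_components <- function(cls, region = NULL, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(cls); nc <- ncol(cls)
  if (is.null(region)) region <- matrix(1L, nr, nc)
  valid <- !is.na(cls) & !is.na(region)
  n <- nr * nc
  lab <- seq_len(n)
  lab[!valid] <- NA_integer_
  idx <- matrix(seq_len(n), nr, nc)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  # Precompute mergeable neighbour pairs (a, b): same class, same region.
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (s in shifts) {
    dr <- s[1L]; dc <- s[2L]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- as.vector(idx[r1, c1, drop = FALSE])
    b <- as.vector(idx[r1 + dr, c1 + dc, drop = FALSE])
    ok <- valid[a] & valid[b] & cls[a] == cls[b] & region[a] == region[b]
    pairs_a <- c(pairs_a, a[ok]); pairs_b <- c(pairs_b, b[ok])
  }
  repeat {
    changed <- FALSE
    if (length(pairs_a)) {
      la <- lab[pairs_a]; lb <- lab[pairs_b]
      mn <- pmin(la, lb)
      upd <- c(pairs_a[la > mn], pairs_b[lb > mn])
      val <- c(mn[la > mn], mn[lb > mn])
      if (length(upd)) {
        # in case of duplicate targets keep the minimum
        o <- order(upd, val)
        upd <- upd[o]; val <- val[o]
        first <- !duplicated(upd)
        lab[upd[first]] <- val[first]
        changed <- TRUE
      }
    }
    # pointer jumping to collapse label chains
    repeat {
      nxt <- lab[lab]
      if (identical(nxt, lab)) break
      lab <- nxt
    }
    if (!changed) break
  }
  out <- matrix(NA_integer_, nr, nc)
  out[valid] <- match(lab[valid], sort(unique(lab[valid])))
  out
}

# Exposed-edge perimeter per cell: edges to different class/region/nodata or
# grid boundary, in cell-edge units (rook directions only).
cell_perimeters <- function(cls, region = NULL) {
  nr <- nrow(cls); nc <- ncol(cls)
  if (is.null(region)) region <- matrix(1L, nr, nc)
  valid <- !is.na(cls) & !is.na(region)
  per <- matrix(0L, nr, nc)
  for (s in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    dr <- s[1L]; dc <- s[2L]
    nb_cls <- matrix(NA_integer_, nr, nc)
    nb_reg <- matrix(NA_integer_, nr, nc)
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    nb_cls[r1, c1] <- cls[r1 + dr, c1 + dc]
    nb_reg[r1, c1] <- region[r1 + dr, c1 + dc]
    exposed <- valid & (is.na(nb_cls) | nb_cls != cls |
                          is.na(nb_reg) | nb_reg != region)
    per <- per + exposed
  }
  per[!valid] <- NA_integer_
  per
}

#' Label patches of a land-use window
#'
#' Connected components of equal-class cells. Perimeters count exposed cell
#' edges: edges shared with another class, with nodata, or with the window
#' boundary.
#'
#' @param window a `landuse_grid` (or bare integer matrix).
#' @param connectivity 4 or 8 (default 8, the FRAGSTATS convention).
#' @return a `patch_set`: data.frame (patch, class, area, perimeter) plus the
#'   label matrix as attribute `labels`; `area` in cells, `perimeter` in
#'   cell-edge units.
#' @export
label_patches <- function(window, connectivity = 8L) {
  cls <- if (inherits(window, "eco_grid")) window$values else as.matrix(window)
  storage.mode(cls) <- "integer"
  if (all(is.na(cls))) stop("empty window: no valid cells")
  lab <- label_components(cls, connectivity = connectivity)
  per <- cell_perimeters(cls)
  keep <- !is.na(lab)
  area <- as.vector(rowsum(rep(1L, sum(keep)), lab[keep]))
  perim <- as.vector(rowsum(as.double(per[keep]), lab[keep]))
  pclass <- cls[keep][!duplicated(lab[keep])]
  pclass <- pclass[order(unique(lab[keep]))]
  ps <- data.frame(patch = seq_along(area), class = pclass,
                   area = area, perimeter = perim)
  attr(ps, "labels") <- lab
  attr(ps, "connectivity") <- connectivity
  class(ps) <- c("patch_set", "data.frame")
  ps
}

# ---- scalar metrics -------------------------------------------------------

#' Shannon's diversity index from class shares
#'
#' `SHDI = -sum(p_i log p_i)` over classes with positive share. A single
#' class (or empty input) gives 0.
#'
#' @param shares numeric vector of non-negative class shares.
#' @return SHDI in `[0, log(number of classes)]`.
#' @export
shdi <- function(shares) {
  p <- shares[!is.na(shares) & shares > 0]
  if (!length(p)) return(0)
  -sum(p * log(p))
}

#' Area-weighted mean patch fractal dimension
#'
#' `AWMPFD = sum over patches of 2 log(0.25 p) / log(a) * a / A`. Single-cell
#' patches (a = 1, log a = 0) contribute the geometric lower bound 1.0.
#'
#' @param patches a `patch_set` (possibly restricted to one class).
#' @param window_area total area A (cells) used for the weights; defaults to
#'   the summed patch area.
#' @return AWMPFD (>= 1 for physical geometries).
#' @export
awmpfd <- function(patches, window_area = sum(patches$area)) {
  if (!nrow(patches)) stop("empty patch set")
  a <- patches$area; p <- patches$perimeter
  fd <- ifelse(a <= 1, 1, 2 * log(0.25 * p) / log(a))
  sum(fd * a / window_area)
}

#' Landscape contagion index (CONTAG)
#'
#' FRAGSTATS contagion on rook cell adjacencies with the double-count
#' convention: `100 * (1 + sum P'_ik log P'_ik / (2 log m))`, where
#' `P'_ik = p_i * g_ik / sum_k g_ik` and m is the number of classes present.
#' A single-class window returns 100 (maximal aggregation convention).
#'
#' @param window a `landuse_grid` or integer matrix.
#' @return CONTAG in `[0, 100]`.
#' @export
contagion <- function(window) {
  cls <- if (inherits(window, "eco_grid")) window$values else as.matrix(window)
  storage.mode(cls) <- "integer"
  valid <- !is.na(cls)
  if (sum(valid) < 2L) stop("contagion needs at least 2 valid cells")
  tab <- adjacency_tally(cls)
  p <- tabulate(cls[valid], nbins = N_CLASSES) / sum(valid)
  contagion_from_tally(tab, p)
}

# Double-counted rook adjacency matrix g (6x6) for one window.
adjacency_tally <- function(cls, region = NULL) {
  nr <- nrow(cls); nc <- ncol(cls)
  if (is.null(region)) region <- matrix(1L, nr, nc)
  g <- matrix(0, N_CLASSES, N_CLASSES)
  for (s in list(c(1L, 0L), c(0L, 1L))) {
    dr <- s[1L]; dc <- s[2L]
    r1 <- 1L:(nr - dr); c1 <- 1L:(nc - dc)
    if (dr >= nr || dc >= nc) next
    a <- cls[r1, c1, drop = FALSE]; b <- cls[r1 + dr, c1 + dc, drop = FALSE]
    ra <- region[r1, c1, drop = FALSE]; rb <- region[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & !is.na(ra) & !is.na(rb) & ra == rb
    if (!any(ok)) next
    ia <- a[ok]; ib <- b[ok]
    cnt <- tabulate((ia - 1L) * N_CLASSES + ib, nbins = N_CLASSES^2)
    g <- g + matrix(cnt, N_CLASSES, N_CLASSES, byrow = TRUE)
  }
  g + t(g)  # double-count convention
}

contagion_from_tally <- function(g, p) {
  present <- which(p > 0)
  m <- length(present)
  if (m <= 1L) return(100)
  rs <- rowSums(g)[present]
  acc <- 0
  for (i in seq_along(present)) {
    ci <- present[i]
    if (rs[i] == 0) next
    for (ck in seq_len(N_CLASSES)) {
      pp <- p[ci] * g[ci, ck] / rs[i]
      if (pp > 0) acc <- acc + pp * log(pp)
    }
  }
  100 * (1 + acc / (2 * log(m)))
}

#' Fragmentation index (patch density)
#'
#' Number of patches per unit area (patches / km^2). For the water and forest
#' variants the patch set is restricted to that class before counting, while
#' the area stays the total window area. Zero patches give 0.
#'
#' @param patches a `patch_set` (possibly class-restricted).
#' @param area_km2 total window area in km^2 (> 0).
#' @return patch density.
#' @export
fragmentation_index <- function(patches, area_km2) {
  if (!is.numeric(area_km2) || area_km2 <= 0) stop("area must be positive")
  nrow(patches) / area_km2
}

#' Patch cohesion index for one class
#'
#' `COHESION = (1 - sum(p) / sum(p sqrt(a))) / (1 - 1/sqrt(Z)) * 100` with Z
#' the total number of cells in the window. Returns 0 when the class is
#' absent.
#'
#' @param patches `patch_set` restricted to the focal class.
#' @param total_cells Z, total (valid) cells in the window; must be >= 2.
#' @return COHESION in `[0, 100]`.
#' @export
cohesion <- function(patches, total_cells) {
  if (total_cells < 2) stop("cohesion needs Z >= 2")
  if (!nrow(patches)) return(0)
  p <- patches$perimeter; a <- patches$area
  (1 - sum(p) / sum(p * sqrt(a))) / (1 - 1 / sqrt(total_cells)) * 100
}

# ---- per-unit batch computation ------------------------------------------

#' Eight landscape metrics for every assessment unit
#'
#' Computes, per unit window in isolation: SHDI, AWMPFD, FI1 (all-class patch
#' density), CONT, FI2 / COHESION1 (water), FI3 / COHESION2 (forest). Units
#' with fewer than 2 valid cells get the degenerate conventions CONT = 100,
#' COHESION = 0.
#'
#' @param landuse a `landuse_grid`.
#' @param units an `assessment_grid` from [tessellate()].
#' @param connectivity patch connectivity, 4 or 8.
#' @return data.frame: unit_id, cell_count, SHDI, AWMPFD, FI1, CONT, FI2,
#'   COHESION1, FI3, COHESION2 (NA rows for empty units).
#' @export
unit_metrics <- function(landuse, units, connectivity = 8L) {
  stopifnot(inherits(landuse, "landuse_grid"), inherits(units, "assessment_grid"))
  if (!identical(dim(landuse$values), dim(units$unit_id)))
    stop("landuse and units shapes differ")
  cls <- landuse$values
  reg <- units$unit_id
  nunit <- nrow(units$unit_index)
  zcount <- units$unit_index$cell_count
  area_km2 <- units$unit_index$area_km2

  shares <- class_proportions(landuse, units)
  shdi_v <- apply(shares, 1L, function(p) if (all(is.na(p))) NA_real_ else shdi(p))

  lab <- label_components(cls, region = reg, connectivity = connectivity)
  per <- cell_perimeters(cls, region = reg)
  keep <- !is.na(lab)
  lv <- lab[keep]
  parea <- as.vector(rowsum(rep(1L, length(lv)), lv))
  pper <- as.vector(rowsum(as.double(per[keep]), lv))
  ulab <- sort(unique(lv))
  ord <- order(lv)
  firsts <- ord[!duplicated(lv[ord])]
  pclass <- cls[keep][firsts]
  punit <- reg[keep][firsts]

  fd <- ifelse(parea <= 1, 1, 2 * log(0.25 * pper) / log(parea))
  aw <- rep(NA_real_, nunit)
  s <- rowsum(fd * parea, punit)
  aw[as.integer(rownames(s))] <- s[, 1L] / zcount[as.integer(rownames(s))]

  np_all <- tabulate(punit, nbins = nunit)
  fi1 <- ifelse(area_km2 > 0, np_all / area_km2, NA_real_)

  class_stats <- function(code) {
    sel <- pclass == code
    np <- tabulate(punit[sel], nbins = nunit)
    fi <- ifelse(area_km2 > 0, np / area_km2, NA_real_)
    coh <- numeric(nunit)
    if (any(sel)) {
      sp <- rowsum(pper[sel], punit[sel])
      spa <- rowsum(pper[sel] * sqrt(parea[sel]), punit[sel])
      ids <- as.integer(rownames(sp))
      z <- zcount[ids]
      val <- ifelse(z >= 2,
                    (1 - sp[, 1L] / spa[, 1L]) / (1 - 1 / sqrt(z)) * 100, 0)
      coh[ids] <- val
    }
    coh[zcount == 0] <- NA_real_
    fi[zcount == 0] <- NA_real_
    list(fi = fi, coh = coh)
  }
  water <- class_stats(LANDUSE_CLASSES[["water"]])
  forest <- class_stats(LANDUSE_CLASSES[["forestland"]])

  cont <- unit_contagion(cls, reg, nunit, shares, zcount)

  out <- data.frame(unit_id = units$unit_index$unit_id,
                    cell_count = zcount,
                    SHDI = shdi_v, AWMPFD = aw, FI1 = fi1, CONT = cont,
                    FI2 = water$fi, COHESION1 = water$coh,
                    FI3 = forest$fi, COHESION2 = forest$coh)
  out[zcount == 0, -(1:2)] <- NA_real_
  out
}

# CONTAG for all units at once: tally directed rook adjacencies per
# (unit, class_a, class_b), then evaluate the entropy form per unit.
unit_contagion <- function(cls, reg, nunit, shares, zcount) {
  nr <- nrow(cls); nc <- ncol(cls)
  K <- N_CLASSES
  cnt <- numeric(nunit * K * K)
  for (s in list(c(1L, 0L), c(0L, 1L))) {
    dr <- s[1L]; dc <- s[2L]
    if (dr >= nr || dc >= nc) next
    r1 <- 1L:(nr - dr); c1 <- 1L:(nc - dc)
    a <- cls[r1, c1, drop = FALSE]; b <- cls[r1 + dr, c1 + dc, drop = FALSE]
    ra <- reg[r1, c1, drop = FALSE]; rb <- reg[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & ra == rb
    if (!any(ok)) next
    u <- ra[ok]; ia <- a[ok]; ib <- b[ok]
    # double count: both directions
    id1 <- (u - 1L) * K * K + (ia - 1L) * K + ib
    id2 <- (u - 1L) * K * K + (ib - 1L) * K + ia
    tb <- tabulate(c(id1, id2), nbins = nunit * K * K)
    cnt <- cnt + tb
  }
  g <- array(cnt, dim = c(K, K, nunit))  # g[b, a, u] by index arithmetic
  # index (u-1)*K*K + (ia-1)*K + ib maps to array[(ib), (ia), u]
  out <- rep(NA_real_, nunit)
  for (u in seq_len(nunit)) {
    if (zcount[u] == 0) next
    p <- shares[u, ]
    if (zcount[u] < 2L || sum(p > 0, na.rm = TRUE) <= 1L) { out[u] <- 100; next }
    gu <- t(g[, , u])  # gu[a, b]
    out[u] <- contagion_from_tally(gu, as.numeric(p))
  }
  out
}
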