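# VORS composite indices: EV, EO, ER, PH, HI, and natural-breaks levels.

#' Default resistance / resilience coefficients
#'
#' Per-class coefficients in `[0, 1]` for the resilience index. The source
#' literature cites coefficient tables without printing them; these defaults
#' encode the standard ordering (forest most resistant/resilient,
#' construction least) and are a configuration table, not a measured input.
#'
#' @return 6 x 2 matrix, rows in class-code order, columns resistance,
#'   resilience.
#' @export
default_resilience_coefficients <- function() {
  m <- rbind(farmland = c(0.5, 0.6), forestland = c(0.9, 0.8),
             grassland = c(0.7, 0.7), water = c(0.8, 0.7),
             construction = c(0.2, 0.2), bareland = c(0.3, 0.3))
  colnames(m) <- c("resistance", "resilience")
  m
}

#' Default weights of the eight organisation metrics
#'
#' EO = 0.35 LH + 0.35 LC + 0.30 IPC, decomposed as
#' LH = 0.25 SHDI + 0.10 AWMPFD, LC = 0.25 FI1 + 0.10 CONT,
#' IPC = 0.10 FI2 + 0.05 COHESION1 + 0.10 FI3 + 0.05 COHESION2
#' (all metrics normalised; the three fragmentation metrics inverted). The
#' weights sum to 1.
#'
#' @return named numeric vector of the eight weights.
#' @export
default_eo_weights <- function() {
  c(SHDI = 0.25, AWMPFD = 0.10, FI1 = 0.25, CONT = 0.10,
    FI2 = 0.10, COHESION1 = 0.05, FI3 = 0.10, COHESION2 = 0.05)
}

# Metrics whose ecological direction is "higher = worse organisation".
EO_INVERTED_METRICS <- c("FI1", "FI2", "FI3")

#' Min-max normalisation to [0, 1]
#'
#' `(x - min) / (max - min)` over the stated domain, optionally inverted
#' (`1 - .`) for metrics where high raw values mean poor condition.
#'
#' @param x numeric vector (NA preserved).
#' @param domain_values values defining the min/max domain (default `x`);
#'   pass pooled multi-year values here for temporally comparable scores.
#' @param invert flip the scale after normalising.
#' @return values in `[0, 1]` (clipped for out-of-domain input).
#' @export
minmax_normalize <- function(x, domain_values = x, invert = FALSE) {
  rng <- range(domain_values, na.rm = TRUE)
  if (!is.finite(rng[1L]) || rng[2L] <= rng[1L])
    stop("degenerate normalisation domain: max must exceed min")
  out <- pmin(1, pmax(0, (x - rng[1L]) / (rng[2L] - rng[1L])))
  if (invert) 1 - out else out
}

#' Ecosystem vigour from per-unit mean NDVI
#'
#' EV is the min-max normalised per-unit mean NDVI.
#'
#' @param ndvi a `continuous_grid` with values in `[-1, 1]`.
#' @param units an `assessment_grid`.
#' @param domain_values optional pooled normalisation domain of unit mean
#'   NDVI values.
#' @return data.frame (unit_id, mean_ndvi, EV).
#' @export
compute_ev <- function(ndvi, units, domain_values = NULL) {
  rngv <- range(ndvi$values, na.rm = TRUE)
  if (rngv[1L] < -1 - 1e-9 || rngv[2L] > 1 + 1e-9)
    stop("NDVI values must lie in [-1, 1]")
  zs <- zonal_stat(ndvi, units, "mean")
  if (is.null(domain_values)) domain_values <- zs$value
  data.frame(unit_id = zs$zone, mean_ndvi = zs$value,
             EV = minmax_normalize(zs$value, domain_values))
}

#' Ecosystem organisation from normalised landscape metrics
#'
#' Weighted sum of the eight normalised metrics. Also returns the LH / LC /
#' IPC sub-scores.
#'
#' @param norm_metrics data.frame or matrix with the eight normalised metric
#'   columns named as in [default_eo_weights()].
#' @param weights named weight vector summing to 1.
#' @return data.frame (LH, LC, IPC, EO).
#' @export
compute_eo <- function(norm_metrics, weights = default_eo_weights()) {
  need <- names(default_eo_weights())
  if (!all(need %in% colnames(norm_metrics)))
    stop("missing metric column(s): ",
         paste(setdiff(need, colnames(norm_metrics)), collapse = ", "))
  if (length(weights) != 8L || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be 8 values summing to 1")
  weights <- weights[need]
  m <- as.matrix(as.data.frame(norm_metrics)[, need])
  lh <- m[, "SHDI"] * weights["SHDI"] + m[, "AWMPFD"] * weights["AWMPFD"]
  lc <- m[, "FI1"] * weights["FI1"] + m[, "CONT"] * weights["CONT"]
  ipc <- m[, "FI2"] * weights["FI2"] + m[, "COHESION1"] * weights["COHESION1"] +
    m[, "FI3"] * weights["FI3"] + m[, "COHESION2"] * weights["COHESION2"]
  data.frame(LH = lh, LC = lc, IPC = ipc, EO = lh + lc + ipc)
}

#' Ecosystem resilience from land-cover composition
#'
#' `ER = 0.4 sum_i A_i C_resist_i + 0.6 sum_i A_i C_resil_i` over the six
#' classes, with `A_i` the per-unit area shares.
#'
#' @param shares matrix (units x 6) of class shares summing to 1.
#' @param coeffs 6 x 2 matrix as in [default_resilience_coefficients()].
#' @param w_resist,w_resil the two aspect weights (default 0.4 / 0.6).
#' @return numeric vector of ER values in `[0, 1]`.
#' @export
compute_er <- function(shares, coeffs = default_resilience_coefficients(),
                       w_resist = 0.4, w_resil = 0.6) {
  shares <- as.matrix(shares)
  if (ncol(shares) != N_CLASSES) stop("shares must have 6 class columns")
  coeffs <- as.matrix(coeffs)
  if (!identical(dim(coeffs), c(6L, 2L)) || any(coeffs < 0 | coeffs > 1))
    stop("coefficient table must be 6 x 2 with values in [0, 1]")
  as.vector(w_resist * shares %*% coeffs[, 1L] +
              w_resil * shares %*% coeffs[, 2L])
}

#' Natural ecosystem health index
#'
#' `PH = (EV * EO * ER)^(1/3)` (geometric mean of the three normalised
#' components).
#'
#' @param ev,eo,er numeric vectors in `[0, 1]`.
#' @return PH in `[0, 1]`.
#' @export
compute_ph <- function(ev, eo, er) {
  if (any(ev < 0 | eo < 0 | er < 0, na.rm = TRUE))
    stop("PH components must be non-negative")
  (ev * eo * er)^(1 / 3)
}

#' Overall ecosystem health index
#'
#' `HI = sqrt(PH * CESI)`.
#'
#' @param ph,cesi numeric vectors in `[0, 1]`.
#' @return HI in `[0, 1]`.
#' @export
compute_hi <- function(ph, cesi) {
  if (any(ph < 0 | cesi < 0, na.rm = TRUE))
    stop("HI components must be non-negative")
  sqrt(ph * cesi)
}

# ---- natural breaks -------------------------------------------------------

#' Fisher-Jenks natural breaks
#'
#' Exact optimal 1-D classification minimising the total within-class sum of
#' squared deviations, by dynamic programming over the distinct values
#' (weighted by multiplicity). Inputs with more than `max_bins` distinct
#' values are first binned to `max_bins` quantile bins (bin mean as
#' representative, count as weight); the result is then optimal for the
#' binned problem - exactness at test scale, bounded cost at pipeline scale.
#'
#' @param values numeric vector (NA dropped).
#' @param k number of classes (>= 2).
#' @param max_bins distinct-value cap before quantile pre-binning.
#' @return object of class `level_breaks`: list with `breakpoints` (k - 1
#'   ascending interior cut values: the class maxima of classes 1..k-1),
#'   `k`, `method = "jenks"`, and the achieved within-class SS `wss`.
#' @export
jenks_breaks <- function(values, k, max_bins = 4096L) {
  x <- values[!is.na(values)]
  if (k < 2L) stop("k must be >= 2")
  ux <- sort(unique(x))
  if (length(ux) < k)
    stop("need at least k distinct values for k classes (got ",
         length(ux), " distinct, k = ", k, ")")
  if (length(ux) > max_bins) {
    br <- stats::quantile(x, probs = seq(0, 1, length.out = max_bins + 1L),
                          names = FALSE, type = 7L)
    bin <- findInterval(x, br[-c(1L, length(br))], left.open = TRUE) + 1L
    w <- as.vector(rowsum(rep(1, length(x)), bin))
    v <- as.vector(rowsum(x, bin)) / w
    o <- order(v)
    v <- v[o]; w <- w[o]
    keep <- !duplicated(v)
    w <- as.vector(rowsum(w, cumsum(keep)))
    v <- v[keep]
  } else {
    v <- ux
    w <- as.vector(rowsum(rep(1, length(x)), match(x, ux)))
  }
  m <- length(v)
  cw <- c(0, cumsum(w)); cwv <- c(0, cumsum(w * v)); cwv2 <- c(0, cumsum(w * v^2))
  seg_cost <- function(i, j) {
    # within-SS of segment v[i..j]; i may be a vector
    sw <- cw[j + 1L] - cw[i]
    sv <- cwv[j + 1L] - cwv[i]
    sv2 <- cwv2[j + 1L] - cwv2[i]
    pmax(0, sv2 - sv^2 / sw)
  }
  D <- seg_cost(rep(1L, m), seq_len(m))       # one class
  B <- matrix(0L, m, k)                       # backpointers: segment start
  B[, 1L] <- 1L
  for (cl in 2L:k) {
    Dn <- rep(Inf, m)
    for (j in cl:m) {
      i <- cl:j                               # candidate starts of last class
      tot <- D[i - 1L] + seg_cost(i, j)
      best <- which.min(tot)
      Dn[j] <- tot[best]
      B[j, cl] <- i[best]
    }
    D <- Dn
  }
  # recover class boundaries
  ends <- integer(k)
  j <- m
  for (cl in k:1L) {
    ends[cl] <- j
    j <- B[j, cl] - 1L
  }
  structure(list(breakpoints = v[ends[-k]], k = k, method = "jenks",
                 wss = D[m]),
            class = "level_breaks")
}

#' Fixed-break classifier definition
#'
#' @param breakpoints k - 1 strictly ascending interior cut values.
#' @return a `level_breaks` object with `method = "fixed"`.
#' @export
fixed_breaks <- function(breakpoints) {
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly ascending")
  structure(list(breakpoints = as.numeric(breakpoints),
                 k = length(breakpoints) + 1L, method = "fixed", wss = NA_real_),
            class = "level_breaks")
}

#' Published five-level bounds for the overall health index
#'
#' The fixed classification low (0-0.174), relatively low (0.175-0.254),
#' moderate (0.255-0.324), fairly good (0.325-0.493), excellent (0.494-1).
#'
#' @return a `level_breaks` object.
#' @export
reference_hi_breaks <- function() fixed_breaks(c(0.174, 0.254, 0.324, 0.493))

#' Five ordered level labels
#' @return character vector, level 1 (worst) to 5 (best).
#' @export
level_labels <- function() {
  c("low", "relatively low", "moderate", "fairly good", "excellent")
}

#' Classify values against level breaks
#'
#' Intervals are right-closed: class c covers `(break_{c-1}, break_c]`, the
#' lowest class closed at the minimum (i.e. everything below the first break).
#'
#' @param values numeric vector.
#' @param breaks a `level_breaks` object.
#' @return integer classes 1..k (NA preserved).
#' @export
classify <- function(values, breaks) {
  stopifnot(inherits(breaks, "level_breaks"))
  bp <- breaks$breakpoints
  if (is.unsorted(bp, strictly = TRUE)) stop("breaks must be strictly ascending")
  findInterval(values, bp, left.open = TRUE) + 1L
}
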