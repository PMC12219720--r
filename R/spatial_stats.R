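# Global Moran's I and Getis-Ord Gi* on per-unit values.

#' Build contiguity weights on the unit lattice
#'
#' Rook = edge-adjacent unit blocks, queen adds diagonals. Weights are binary
#' and optionally row-standardised. Units can be dropped (e.g. nodata-only)
#' via `keep`.
#'
#' @param units an `assessment_grid`, or a list with `n_unit_rows` /
#'   `n_unit_cols`.
#' @param scheme "queen" (default) or "rook".
#' @param row_standardise divide each row by its sum (default TRUE).
#' @param include_self add a self-neighbour with weight 1 (required for Gi*;
#'   never use for Moran's I).
#' @param keep logical vector over units; FALSE drops a unit from the graph.
#' @return a `spatial_weights` object: sparse matrix `W` (dgCMatrix), plus
#'   `ids` (unit ids of the rows), `scheme`, `row_standardised`.
#' @export
build_weights <- function(units, scheme = c("queen", "rook"),
                          row_standardise = TRUE, include_self = FALSE,
                          keep = NULL) {
  scheme <- match.arg(scheme)
  nr <- units$n_unit_rows; nc <- units$n_unit_cols
  n <- nr * nc
  if (n < 2L) stop("need at least 2 units")
  if (is.null(keep)) keep <- rep(TRUE, n)
  ids <- which(keep)
  pos <- match(seq_len(n), ids)         # lattice id -> row in W (NA if dropped)
  rowv <- (ids - 1L) %/% nc + 1L
  colv <- (ids - 1L) %% nc + 1L
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (scheme == "queen") shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  ii <- integer(0); jj <- integer(0)
  for (s in shifts) {
    r2 <- rowv + s[1L]; c2 <- colv + s[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (r2[ok] - 1L) * nc + c2[ok]
    p2 <- pos[nb]
    src <- seq_along(ids)[ok]
    good <- !is.na(p2)
    ii <- c(ii, src[good], p2[good])
    jj <- c(jj, p2[good], src[good])
  }
  m <- length(ids)
  if (include_self) { ii <- c(ii, seq_len(m)); jj <- c(jj, seq_len(m)) }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(m, m))
  if (row_standardise) {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- Matrix::Diagonal(x = 1 / rs) %*% W
  }
  structure(list(W = methods::as(W, "generalMatrix"), ids = ids,
                 scheme = scheme, row_standardised = row_standardise,
                 include_self = include_self),
            class = "spatial_weights")
}

#' Global Moran's I with randomisation-assumption inference
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z = x - mean(x)`.
#' The z-score uses the analytic variance under the randomisation assumption
#' (permutation-invariant null); the p-value is two-sided normal. An optional
#' seeded permutation p-value is available.
#'
#' @param values numeric vector aligned with the weights (NA not allowed:
#'   drop missing units when building the weights).
#' @param weights a `spatial_weights` object (no self-neighbours).
#' @param permutations if > 0, also compute a permutation p-value with this
#'   many seeded permutations.
#' @param seed seed for the permutation test.
#' @return list (I, expected, z, p, n, p_perm or NA).
#' @export
morans_i <- function(values, weights, permutations = 0L, seed = 1L) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (isTRUE(weights$include_self)) stop("Moran's I weights must exclude self")
  W <- weights$W
  n <- length(values)
  if (n != nrow(W)) stop("values not aligned with weights")
  if (anyNA(values)) stop("NA values: drop missing units from the weights")
  z <- values - mean(values)
  m2 <- sum(z^2)
  if (m2 == 0) stop("constant values: Moran's I undefined")
  S0 <- sum(W)
  Wz <- as.vector(W %*% z)
  I <- (n / S0) * sum(z * Wz) / m2
  EI <- -1 / (n - 1)
  S1 <- sum((W + Matrix::t(W))@x^2) / 2
  S2 <- sum((Matrix::rowSums(W) + Matrix::colSums(W))^2)
  b2 <- n * sum(z^4) / m2^2
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zscore <- (I - EI) / sqrt(varI)
  p <- 2 * stats::pnorm(-abs(zscore))
  p_perm <- NA_real_
  if (permutations > 0L) {
    perm_I <- with_seed(seed, {
      vapply(seq_len(permutations), function(k) {
        zp <- z[sample.int(n)]
        (n / S0) * sum(zp * as.vector(W %*% zp)) / m2
      }, 0)
    })
    extreme <- sum(abs(perm_I - EI) >= abs(I - EI))
    p_perm <- (extreme + 1) / (permutations + 1)
  }
  list(I = I, expected = EI, z = zscore, p = p, n = n, p_perm = p_perm)
}

#' Getis-Ord Gi* hot/cold-spot z-scores
#'
#' Standard Gi* with self-inclusion:
#' `z_i = (sum_j w_ij x_j - xbar W_i) / (S sqrt((n W2_i - W_i^2) / (n - 1)))`
#' with `xbar` and the population SD `S` over all n units,
#' `W_i = sum_j w_ij`, `W2_i = sum_j w_ij^2`.
#'
#' @param values numeric vector aligned with the weights.
#' @param weights a `spatial_weights` built with `include_self = TRUE`
#'   (binary, not row-standardised, is the conventional choice).
#' @return numeric vector of per-unit z-scores.
#' @export
getis_ord_gstar <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (!isTRUE(weights$include_self)) stop("Gi* weights must include self")
  W <- weights$W
  n <- length(values)
  if (n != nrow(W)) stop("values not aligned with weights")
  if (anyNA(values)) stop("NA values: drop missing units from the weights")
  xbar <- mean(values)
  S <- sqrt(mean(values^2) - xbar^2)
  if (S == 0) stop("constant values: Gi* undefined")
  Wi <- Matrix::rowSums(W)
  W2i <- Matrix::rowSums(W^2)
  num <- as.vector(W %*% values) - xbar * Wi
  den <- S * sqrt(pmax(0, (n * W2i - Wi^2) / (n - 1)))
  num / den
}

HOTSPOT_LEVELS <- c("cold99", "cold95", "cold90", "ns",
                    "hot90", "hot95", "hot99")

#' Classify Gi* z-scores into hot/cold-spot confidence tiers
#'
#' Thresholds +-1.65 (90%), +-1.96 (95%), +-2.58 (99%).
#'
#' @param z numeric vector of Gi* z-scores.
#' @return ordered factor with levels cold99 < cold95 < cold90 < ns < hot90 <
#'   hot95 < hot99.
#' @export
classify_hotspots <- function(z) {
  tier <- findInterval(abs(z), c(1.65, 1.96, 2.58))  # 0 = ns .. 3 = 99%
  out <- rep("ns", length(z))
  hot <- z > 0
  lab_hot <- c("hot90", "hot95", "hot99")
  lab_cold <- c("cold90", "cold95", "cold99")
  sig <- tier > 0 & !is.na(z)
  out[sig] <- ifelse(hot[sig], lab_hot[tier[sig]], lab_cold[tier[sig]])
  out[is.na(z)] <- NA
  factor(out, levels = HOTSPOT_LEVELS, ordered = TRUE)
}
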