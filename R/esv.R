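# Ecosystem-service value: ESV, area-specific AESV, and normalised CESI.

#' Default ecosystem-service value coefficients
#'
#' Per-class service value per km^2 (dimensionless equivalents). The
#' equivalent-factor literature supplies regional coefficient tables; none is
#' reproduced here, so the default is an illustrative ordering
#' water >> forest > grassland > farmland > bare > construction = 0. All
#' package results that matter are invariant to a positive rescaling of the
#' whole table (CESI is min-max normalised).
#'
#' @return named numeric vector over the six land-use classes.
#' @export
default_esv_coefficients <- function() {
  c(farmland = 1, forestland = 3, grassland = 2,
    water = 8, construction = 0, bareland = 0.2)
}

#' Ecosystem-service value per unit
#'
#' `ESV = sum_i U_i VC_i` and `AESV = ESV / sum_i U_i` over the six classes.
#'
#' @param areas matrix (units x 6) of per-class areas `U_i` (km^2); may be
#'   shares times unit area.
#' @param coeffs named numeric vector of per-class coefficients `VC_i`
#'   (non-negative, in class-code order farmland..bareland).
#' @return data.frame (unit, ESV, AESV, missing); units with zero total area
#'   are flagged missing.
#' @export
compute_esv <- function(areas, coeffs = default_esv_coefficients()) {
  areas <- as.matrix(areas)
  if (ncol(areas) != N_CLASSES) stop("areas must have 6 class columns")
  if (length(coeffs) != N_CLASSES || any(coeffs < 0, na.rm = TRUE))
    stop("coeffs must be 6 non-negative values")
  if (!is.null(names(coeffs)))
    coeffs <- coeffs[names(LANDUSE_CLASSES)]
  if (any(is.na(coeffs))) stop("coeffs missing a land-use class")
  tot <- rowSums(areas)
  esv <- as.vector(areas %*% coeffs)
  aesv <- ifelse(!is.na(tot) & tot > 0, esv / tot, NA_real_)
  esv[is.na(aesv)] <- NA_real_
  data.frame(unit = seq_len(nrow(areas)), ESV = esv, AESV = aesv,
             missing = is.na(aesv))
}

#' Comprehensive ecosystem service index (min-max normalised AESV)
#'
#' `CESI = (AESV - min) / (max - min)`, clipped to `[0, 1]` for values
#' outside the normalisation domain. The domain is taken from `domain_values`
#' (default: the input itself), which allows pooling across years.
#'
#' @param aesv numeric vector of AESV values (NA allowed).
#' @param domain_values values defining min/max; defaults to `aesv`.
#' @return CESI in `[0, 1]` (NA preserved).
#' @export
compute_cesi <- function(aesv, domain_values = aesv) {
  rng <- range(domain_values, na.rm = TRUE)
  if (!is.finite(rng[1L]) || rng[2L] <= rng[1L])
    stop("degenerate AESV domain: max must exceed min")
  pmin(1, pmax(0, (aesv - rng[1L]) / (rng[2L] - rng[1L])))
}
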