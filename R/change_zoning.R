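# Temporal level-change typing and county-level control-zone assignment.

CHANGE_TYPES <- c("continuous decline", "fluctuating decline", "stable",
                  "fluctuating rise", "continuous rise")

#' Classify a level trajectory into a dynamic-change type
#'
#' With deltas `dL_t = L_{t+1} - L_t` and cumulative change `S_L = sum(dL)`:
#' continuous decline (all dL <= 0, S_L < 0), fluctuating decline (mixed
#' signs, S_L < 0), stable (all dL = 0), fluctuating rise (mixed signs,
#' S_L > 0), continuous rise (all dL >= 0, S_L > 0). Mixed-sign net-zero
#' trajectories fall outside the published predicates and are typed stable
#' with `fluctuating_neutral = TRUE` (gap rule).
#'
#' @param levels integer vector of ordinal levels 1-5, length >= 2.
#' @return a `change_type` list: type (factor over the five types), S_L,
#'   deltas, fluctuating_neutral flag.
#' @export
classify_change_type <- function(levels) {
  if (length(levels) < 2L) stop("need at least 2 timepoints")
  if (any(is.na(levels)) || any(levels < 1L | levels > 5L))
    stop("levels must be ordinal 1-5 without NA")
  d <- diff(levels)
  s <- sum(d)
  neutral <- FALSE
  type <- if (all(d == 0)) "stable"
  else if (s < 0 && all(d <= 0)) "continuous decline"
  else if (s < 0) "fluctuating decline"
  else if (s > 0 && all(d >= 0)) "continuous rise"
  else if (s > 0) "fluctuating rise"
  else { neutral <- TRUE; "stable" }
  structure(list(type = factor(type, levels = CHANGE_TYPES), S_L = s,
                 deltas = d, fluctuating_neutral = neutral),
            class = "change_type")
}

#' Change types for a matrix of trajectories
#'
#' @param level_matrix integer matrix, rows = spatial units, columns =
#'   timepoints in order.
#' @return data.frame (id, type, S_L, fluctuating_neutral).
#' @export
classify_change_types <- function(level_matrix) {
  level_matrix <- as.matrix(level_matrix)
  res <- apply(level_matrix, 1L, classify_change_type)
  data.frame(id = seq_len(nrow(level_matrix)),
             type = factor(vapply(res, function(r) as.character(r$type), ""),
                           levels = CHANGE_TYPES),
             S_L = vapply(res, function(r) as.integer(r$S_L), 0L),
             fluctuating_neutral = vapply(res, function(r) r$fluctuating_neutral,
                                          FALSE))
}

LEVEL_CLASSES <- c("Ia", "IIa", "IIIa", "IVa", "Va")   # Ia = highest health
TYPE_CLASSES <- c("Ib", "IIb", "IIIb", "IVb", "Vb")    # Ib = continuous rise
ZONES <- c("emergency control", "strict control", "dynamic regulation",
           "preventive management", "sensitive monitoring")

#' Map ordinal health levels (1 low .. 5 excellent) to level classes Ia..Va
#'
#' Ia is the highest-health class, Va the lowest.
#' @param level integer 1-5.
#' @return factor over Ia..Va.
#' @export
level_to_class <- function(level) {
  stopifnot(all(level %in% 1:5))
  factor(LEVEL_CLASSES[6L - level], levels = LEVEL_CLASSES)
}

#' Map change types to type classes Ib..Vb
#'
#' Ib = continuous rise, IIb = fluctuating rise, IIIb = stable, IVb =
#' fluctuating decline, Vb = continuous decline. This coding (reverse of the
#' type numbering used for the change classifier itself) is the one under
#' which every control-zone row is internally consistent with its verbal
#' description and the published 23 level-type combinations emerge with two
#' natural gaps.
#'
#' @param type character or factor over the five change types.
#' @return factor over Ib..Vb.
#' @export
change_type_to_class <- function(type) {
  map <- c("continuous rise" = "Ib", "fluctuating rise" = "IIb",
           "stable" = "IIIb", "fluctuating decline" = "IVb",
           "continuous decline" = "Vb")
  out <- map[as.character(type)]
  if (anyNA(out)) stop("unknown change type")
  factor(unname(out), levels = TYPE_CLASSES)
}

#' Default control-zone lookup (23 level-type combinations)
#'
#' The published table, with the duplicated preventive-row entries read as
#' IIa-IIb / IIa-IIIb (the only reading yielding 23 distinct pairs that match
#' the row description "high current health level"). Two of the 25 pairs are
#' not covered and fall back (flagged) in [assign_control_zone()].
#'
#' @return data.frame (level_class, type_class, zone).
#' @export
default_zone_lookup <- function() {
  rows <- list(
    # emergency: low current health, continuously declining
    c("IVa", "Vb"), c("Va", "Vb"), c("Va", "IVb"), c("IVa", "IVb"),
    # strict: low current health, tending to stable
    c("Va", "IIb"), c("Va", "IIIb"), c("IVa", "Ib"), c("IVa", "IIb"),
    c("IVa", "IIIb"),
    # dynamic: mid health, any trend
    c("IIIa", "Ib"), c("IIIa", "IIb"), c("IIIa", "IIIb"), c("IIIa", "IVb"),
    c("IIIa", "Vb"),
    # preventive: high health, declining or stable
    c("Ia", "IIb"), c("Ia", "IIIb"), c("Ia", "IVb"), c("IIa", "IIb"),
    c("IIa", "IIIb"), c("IIa", "IVb"),
    # sensitive: high health, drastic change
    c("Ia", "Ib"), c("IIa", "Ib"), c("IIa", "Vb"))
  zone <- rep(ZONES, times = c(4L, 5L, 5L, 6L, 3L))
  data.frame(level_class = vapply(rows, `[`, "", 1L),
             type_class = vapply(rows, `[`, "", 2L),
             zone = zone)
}

# Fallbacks for the 2 uncovered pairs: nearest row description.
ZONE_FALLBACKS <- data.frame(
  level_class = c("Ia", "Va"),
  type_class = c("Vb", "Ib"),
  zone = c("sensitive monitoring", "strict control"))

#' Assign a control zone from level class and type class
#'
#' @param level_class factor/character Ia..Va.
#' @param type_class factor/character Ib..Vb.
#' @param lookup lookup table as from [default_zone_lookup()].
#' @return data.frame (level_class, type_class, zone, fallback); `fallback`
#'   is TRUE where the pair is not in the lookup and a flagged nearest-row
#'   fallback fired.
#' @export
assign_control_zone <- function(level_class, type_class,
                                lookup = default_zone_lookup()) {
  if (!all(c("level_class", "type_class", "zone") %in% names(lookup)))
    stop("malformed lookup: need level_class, type_class, zone columns")
  if (!all(lookup$level_class %in% LEVEL_CLASSES) ||
      !all(lookup$type_class %in% TYPE_CLASSES) ||
      !all(lookup$zone %in% ZONES))
    stop("malformed lookup: invalid class or zone labels")
  key <- paste(lookup$level_class, lookup$type_class)
  if (anyDuplicated(key)) stop("malformed lookup: overlapping entries")
  level_class <- as.character(level_class)
  type_class <- as.character(type_class)
  if (!all(level_class %in% LEVEL_CLASSES) || !all(type_class %in% TYPE_CLASSES))
    stop("invalid level or type class")
  qkey <- paste(level_class, type_class)
  hit <- match(qkey, key)
  fb <- match(qkey, paste(ZONE_FALLBACKS$level_class, ZONE_FALLBACKS$type_class))
  zone <- ifelse(!is.na(hit), lookup$zone[hit], ZONE_FALLBACKS$zone[fb])
  if (anyNA(zone)) stop("pair not covered by lookup or fallbacks")
  data.frame(level_class = factor(level_class, levels = LEVEL_CLASSES),
             type_class = factor(type_class, levels = TYPE_CLASSES),
             zone = factor(zone, levels = ZONES),
             fallback = is.na(hit))
}

#' County-level health classes from unit values
#'
#' County score = area-weighted mean of the per-unit index (weights = valid
#' cell counts); counties are then classed 1..5 by natural breaks on the
#' scores and mapped so that the highest-score group is Ia.
#'
#' @param values per-unit index values (e.g. HI).
#' @param county per-unit county id.
#' @param weights per-unit weights (cell counts); default equal.
#' @param score_breaks optional precomputed `level_breaks` for the scores
#'   (e.g. pooled across years); default computes Jenks on these scores.
#' @return data.frame (county, score, level, level_class); level 5 = best.
#' @export
county_level_class <- function(values, county, weights = NULL,
                               score_breaks = NULL) {
  keep <- !is.na(values) & !is.na(county)
  if (is.null(weights)) weights <- rep(1, length(values))
  v <- values[keep]; cty <- county[keep]; w <- weights[keep]
  if (!length(v)) stop("no valid units")
  sw <- rowsum(w, cty)
  swv <- rowsum(w * v, cty)
  score <- swv[, 1L] / sw[, 1L]
  ids <- as.integer(rownames(sw))
  if (is.null(score_breaks)) {
    if (length(unique(score)) < 5L)
      stop("fewer than 5 distinct county scores: cannot form 5 classes by ",
           "natural breaks; supply score_breaks or pool more data")
    score_breaks <- jenks_breaks(score, 5L)
  }
  lev <- classify(score, score_breaks)
  data.frame(county = ids, score = as.vector(score), level = lev,
             level_class = level_to_class(lev))
}
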