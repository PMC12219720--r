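# Config-driven orchestration of the full assessment over T timepoints.

#' Default run configuration
#'
#' A complete, validated configuration for a synthetic run at desk scale.
#' Coefficient tables carry the package defaults; every entry can be
#' overridden before calling [run_pipeline()].
#'
#' @param seed master seed.
#' @return a nested list (class `run_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    scenario = list(shape = c(200L, 200L), cell_size = 1, unit_km = 3,
                    T = 5L, n_counties = 64L,
                    class_targets = default_class_targets(),
                    transition_matrix = default_transition_matrix(),
                    designed_q = default_designed_q(),
                    hotspot = TRUE, hotspot_units = 8L, hotspot_contrast = 3,
                    correlation_range = 8),
    input_dir = NULL,                      # set to read rasters instead
    unit_km = 3,
    normalisation = "pooled",              # or "per-year"
    vc_table = default_esv_coefficients(),
    resilience_table = default_resilience_coefficients(),
    eo_weights = default_eo_weights(),
    connectivity = 8L,
    weights_scheme = "queen",
    level_method = "jenks",                # or "fixed" (published HI bounds)
    fixed_breaks = c(0.174, 0.254, 0.324, 0.493),
    geodetector = list(k = 5L, method = "jenks", tol = 1e-6),
    zone_lookup = default_zone_lookup()
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks completeness of all coefficient tables (all six classes), weights,
#' and settings, before any computation.
#'
#' @param config a `run_config` list.
#' @return invisibly TRUE; errors name the offending key.
#' @export
validate_config <- function(config) {
  need <- c("seed", "vc_table", "resilience_table", "eo_weights",
            "normalisation", "geodetector", "zone_lookup", "unit_km")
  for (k in need)
    if (is.null(config[[k]])) stop_stage("config", "missing key: ", k)
  if (length(config$vc_table) != 6L || anyNA(config$vc_table))
    stop_stage("config", "vc_table must cover all 6 land-use classes")
  if (!identical(dim(as.matrix(config$resilience_table)), c(6L, 2L)))
    stop_stage("config", "resilience_table must be 6 x 2")
  if (abs(sum(config$eo_weights) - 1) > 1e-9)
    stop_stage("config", "eo_weights must sum to 1")
  if (!config$normalisation %in% c("pooled", "per-year"))
    stop_stage("config", "normalisation must be 'pooled' or 'per-year'")
  if (is.null(config$scenario) && is.null(config$input_dir))
    stop_stage("config", "either scenario params or input_dir required")
  invisible(TRUE)
}

# Read a scenario previously written with write_scenario().
read_scenario_dir <- function(dir, unit_km) {
  man <- jsonlite::read_json(file.path(dir, "scenario_manifest.json"),
                             simplifyVector = TRUE)
  T <- man$T
  lus <- lapply(seq_len(T), function(t)
    read_raster(file.path(dir, sprintf("landuse_t%d.asc", t)), "landuse"))
  ndvi <- lapply(seq_len(T), function(t)
    read_raster(file.path(dir, sprintf("ndvi_t%d.asc", t)), "continuous"))
  drivers <- lapply(man$drivers, function(id)
    read_raster(file.path(dir, paste0(id, ".asc")), "continuous"))
  names(drivers) <- man$drivers
  counties <- read_raster(file.path(dir, "counties.asc"), "continuous")
  do.call(check_grid_stack, c(lus, ndvi, drivers, list(counties)))
  list(landuse_series = lus, ndvi_series = ndvi, drivers = drivers,
       county_labels = matrix(as.integer(counties$values),
                              nrow(counties$values)),
       units = tessellate(lus[[1L]], unit_km),
       years = seq_len(T))
}

#' Run the full assessment pipeline
#'
#' Stages: ingest (synthetic or from disk) -> tessellation -> landscape
#' metrics -> VORS indices and levels -> spatial statistics (Moran's I, Gi*)
#' -> Geodetector factors and interactions -> change typing -> county zoning.
#' All outputs are CSV tables plus a JSON manifest recording the config hash
#' and seed; re-running the same config reproduces every output byte for
#' byte.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param out_dir output directory.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the main result tables and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf("[%s] %s",
                                                   format(Sys.time(), "%H:%M:%S"),
                                                   paste0(...)))
  t0 <- proc.time()[["elapsed"]]

  # -- ingest ---------------------------------------------------------------
  say("ingest: building inputs")
  if (!is.null(config$input_dir)) {
    sc <- read_scenario_dir(config$input_dir, config$unit_km)
  } else {
    sc <- do.call(generate_scenario,
                  c(config$scenario[setdiff(names(config$scenario), "unit_km")],
                    list(unit_km = config$unit_km, seed = config$seed)))
  }
  units <- sc$units
  T <- length(sc$landuse_series)
  years <- seq_len(T)
  nunit <- nrow(units$unit_index)
  pooled <- identical(config$normalisation, "pooled")

  # -- landscape metrics & composition --------------------------------------
  say("metrics: landscape metrics for ", nunit, " units x ", T, " timepoints")
  metric_names <- names(default_eo_weights())
  raw_list <- vector("list", T)
  shares_list <- vector("list", T)
  for (t in years) {
    raw_list[[t]] <- unit_metrics(sc$landuse_series[[t]], units,
                                  config$connectivity)
    shares_list[[t]] <- class_proportions(sc$landuse_series[[t]], units)
  }
  raw <- data.table::rbindlist(lapply(years, function(t)
    data.table::data.table(year = t, raw_list[[t]])))

  # -- indices --------------------------------------------------------------
  say("indices: EV / EO / ER / PH / AESV / CESI / HI")
  norm <- data.table::copy(raw)
  for (mn in metric_names) {
    inv <- mn %in% EO_INVERTED_METRICS
    if (pooled) {
      norm[[mn]] <- minmax_normalize(raw[[mn]], raw[[mn]], invert = inv)
    } else {
      for (t in years) {
        i <- raw$year == t
        norm[[mn]][i] <- minmax_normalize(raw[[mn]][i], invert = inv)
      }
    }
  }
  eo <- compute_eo(norm, config$eo_weights)$EO

  ndvi_means <- unlist(lapply(years, function(t)
    zonal_stat(sc$ndvi_series[[t]], units, "mean")$value))
  ev <- if (pooled) minmax_normalize(ndvi_means, ndvi_means)
  else unlist(lapply(years, function(t) {
    i <- (t - 1L) * nunit + seq_len(nunit)
    minmax_normalize(ndvi_means[i])
  }))

  er_raw <- unlist(lapply(years, function(t)
    compute_er(shares_list[[t]], config$resilience_table)))
  er <- if (pooled) minmax_normalize(er_raw, er_raw)
  else unlist(lapply(years, function(t) {
    i <- (t - 1L) * nunit + seq_len(nunit)
    minmax_normalize(er_raw[i])
  }))

  area_mat <- units$unit_index$area_km2
  aesv <- unlist(lapply(years, function(t) {
    areas <- shares_list[[t]] * area_mat
    compute_esv(areas, config$vc_table)$AESV
  }))
  cesi <- if (pooled) compute_cesi(aesv, aesv)
  else unlist(lapply(years, function(t) {
    i <- (t - 1L) * nunit + seq_len(nunit)
    compute_cesi(aesv[i])
  }))

  ph <- compute_ph(ev, eo, er)
  hi <- compute_hi(ph, cesi)

  ind <- data.table::data.table(
    unit_id = rep(units$unit_index$unit_id, T),
    year = rep(years, each = nunit),
    EV = ev, EO = eo, ER = er, PH = ph, AESV = aesv, CESI = cesi, HI = hi)

  # -- levels ---------------------------------------------------------------
  say("levels: five-level classification (", config$level_method, ")")
  if (identical(config$level_method, "fixed")) {
    hi_breaks <- fixed_breaks(config$fixed_breaks)
  } else {
    hi_breaks <- jenks_breaks(ind$HI, 5L)
  }
  ind$level <- classify(ind$HI, hi_breaks)
  ind$level_label <- level_labels()[ind$level]

  # -- spatial statistics ---------------------------------------------------
  say("spatial: Moran's I and Gi* per year")
  valid_units <- units$unit_index$cell_count > 0
  Wq <- build_weights(units, config$weights_scheme, row_standardise = TRUE,
                      keep = valid_units)
  Wg <- build_weights(units, config$weights_scheme, row_standardise = FALSE,
                      include_self = TRUE, keep = valid_units)
  sp_rows <- list(); hot <- rep(NA_character_, nrow(ind))
  hotz <- rep(NA_real_, nrow(ind))
  for (t in years) {
    for (v in c("PH", "CESI", "HI")) {
      x <- ind[[v]][ind$year == t][valid_units]
      mi <- morans_i(x, Wq)
      sp_rows[[length(sp_rows) + 1L]] <-
        data.table::data.table(year = t, variable = v, I = mi$I, z = mi$z,
                               p = mi$p)
      gz <- getis_ord_gstar(x, Wg)
      rows <- which(ind$year == t)[valid_units]
      if (v == "HI") {
        hotz[rows] <- gz
        hot[rows] <- as.character(classify_hotspots(gz))
      }
    }
  }
  spatial <- data.table::rbindlist(sp_rows)
  ind$gi_z <- hotz
  ind$hotspot <- hot

  # -- geodetector ----------------------------------------------------------
  say("geodetector: ", length(sc$drivers), " factors, ",
      choose(length(sc$drivers), 2), " interactions x ", T, " years")
  gd <- config$geodetector
  drv_units <- lapply(sc$drivers, function(g) zonal_stat(g, units, "mean")$value)
  drv_strata <- lapply(drv_units, function(x)
    discretize(x, gd$k, gd$method))
  fac_rows <- list(); int_rows <- list()
  ids <- names(sc$drivers)
  for (t in years) {
    yv <- ind$HI[ind$year == t]
    qs <- list()
    for (id in ids) {
      qr <- factor_q(yv, drv_strata[[id]])
      qs[[id]] <- qr$q
      fac_rows[[length(fac_rows) + 1L]] <-
        data.table::data.table(year = t, driver = id, q = qr$q, p = qr$p,
                               stars = q_stars(qr$p))
    }
    if (length(ids) > 1L) {
      for (a in seq_len(length(ids) - 1L)) for (b in (a + 1L):length(ids)) {
        q12 <- interaction_q(yv, drv_strata[[ids[a]]], drv_strata[[ids[b]]])$q
        int_rows[[length(int_rows) + 1L]] <- data.table::data.table(
          year = t, driver1 = ids[a], driver2 = ids[b],
          q1 = qs[[ids[a]]], q2 = qs[[ids[b]]], q12 = q12,
          type = classify_interaction(qs[[ids[a]]], qs[[ids[b]]], q12, gd$tol))
      }
    }
  }
  factors <- data.table::rbindlist(fac_rows)
  interactions <- data.table::rbindlist(int_rows)

  # -- change typing --------------------------------------------------------
  say("change: level-change typing per unit")
  lev_mat <- matrix(ind$level, nrow = nunit, ncol = T)
  ok_traj <- !apply(lev_mat, 1L, anyNA)
  changes <- data.table::data.table(unit_id = units$unit_index$unit_id,
                                    type = NA_character_, S_L = NA_integer_,
                                    fluctuating_neutral = NA)
  if (any(ok_traj)) {
    ct <- classify_change_types(lev_mat[ok_traj, , drop = FALSE])
    changes$type[ok_traj] <- as.character(ct$type)
    changes$S_L[ok_traj] <- ct$S_L
    changes$fluctuating_neutral[ok_traj] <- ct$fluctuating_neutral
  }

  # -- county zoning --------------------------------------------------------
  say("zoning: county level classes and control zones")
  # county id per unit: majority county label among the unit's cells
  cty_of_unit <- zonal_stat(
    continuous_grid(sc$county_labels,
                    cell_size = units$cell_size),
    units, "majority")$value
  w_units <- units$unit_index$cell_count
  keep_u <- !is.na(cty_of_unit)
  scores <- lapply(years, function(t) {
    hi_t <- ind$HI[ind$year == t][keep_u]
    sw <- rowsum(w_units[keep_u], cty_of_unit[keep_u])
    swv <- rowsum(w_units[keep_u] * hi_t, cty_of_unit[keep_u])
    as.vector(swv / sw)
  })
  score_mat <- do.call(cbind, scores)
  # pooled natural breaks over county-year scores: levels comparable in time
  cty_breaks <- jenks_breaks(as.vector(score_mat), 5L)
  cty_lev <- matrix(classify(as.vector(score_mat), cty_breaks),
                    nrow = nrow(score_mat))
  cty_ids <- as.integer(rownames(rowsum(w_units[keep_u], cty_of_unit[keep_u])))
  cty_types <- classify_change_types(cty_lev)
  final_lev <- cty_lev[, T]
  za <- assign_control_zone(level_to_class(final_lev),
                            change_type_to_class(cty_types$type),
                            config$zone_lookup)
  zoning <- data.table::data.table(
    county = cty_ids,
    year_range = sprintf("%d-%d", years[1L], years[T]),
    score_final = score_mat[, T],
    level = final_lev,
    level_class = as.character(za$level_class),
    change_type = as.character(cty_types$type),
    type_class = as.character(za$type_class),
    zone = as.character(za$zone),
    fallback = za$fallback)

  # -- outputs --------------------------------------------------------------
  say("write: tables and manifest")
  paths <- c(indicators = "indicators.csv", metrics = "landscape_metrics.csv",
             spatial = "spatial_stats.csv", factors = "geodetector_factors.csv",
             interactions = "geodetector_interactions.csv",
             changes = "change_types.csv", zoning = "county_zones.csv")
  data.table::fwrite(ind, file.path(out_dir, paths["indicators"]))
  data.table::fwrite(raw, file.path(out_dir, paths["metrics"]))
  data.table::fwrite(spatial, file.path(out_dir, paths["spatial"]))
  data.table::fwrite(factors, file.path(out_dir, paths["factors"]))
  data.table::fwrite(interactions, file.path(out_dir, paths["interactions"]))
  data.table::fwrite(changes, file.path(out_dir, paths["changes"]))
  data.table::fwrite(zoning, file.path(out_dir, paths["zoning"]))

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config_digestable(config), cfg_file, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package = "vorshealth",
    version = as.character(utils::packageVersion("vorshealth")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    hi_md5 = digest_vector(ind$HI),
    levels_from_hi_md5 = digest_vector(ind$level),
    breaks = hi_breaks$breakpoints,
    n_units = nunit, T = T,
    outputs = as.list(unname(tools::md5sum(file.path(out_dir, paths)))))
  names(manifest$outputs) <- paths
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say(sprintf("done in %.1f s", proc.time()[["elapsed"]] - t0))
  invisible(list(indicators = ind, metrics = raw, spatial = spatial,
                 factors = factors, interactions = interactions,
                 changes = changes, zoning = zoning, breaks = hi_breaks,
                 manifest = manifest, units = units, scenario = sc))
}

# Serialisable view of a config (matrices to lists) for hashing.
config_digestable <- function(config) {
  rapply(unclass(config), function(x) {
    if (is.matrix(x)) as.list(as.data.frame(x)) else x
  }, how = "replace")
}

# md5 of a numeric vector via its full-precision text form.
digest_vector <- function(x) {
  f <- tempfile()
  writeLines(sprintf("%.17g", as.double(x)), f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}
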