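# File formats and the pipeline driver. All tabular artifacts are RFC-4180
# CSV with a mandatory header; timestamps are ISO-8601 UTC; coordinates are
# written at 6 decimal places (about 0.1 m) while internals keep full
# precision. Cluster centroids and monthly isopleths can be exported as
# GeoJSON (RFC 7946).

#' Read a fix table from CSV
#'
#' Expects the columns `female_id,timestamp_iso8601,lon,lat` (extra columns
#' are ignored). Rows with unparseable timestamps or out-of-range
#' coordinates are dropped and counted; fixes are grouped by female and
#' time-sorted. Duplicate timestamps within a female are an error.
#'
#' @param path CSV file path.
#' @param quiet suppress the malformed-row message.
#' @return named list of trajectories; attribute `"n_rejected"` holds the
#'   dropped-row count.
#' @export
read_fixes <- function(path, quiet = FALSE) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("female_id", "timestamp_iso8601", "lon", "lat")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("fix CSV missing columns: ", paste(miss, collapse = ", "))
  t <- as.POSIXct(raw$timestamp_iso8601, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad <- is.na(t) | is.na(lon) | is.na(lat) | abs(lon) > 180 | abs(lat) > 90
  if (any(bad) && !quiet)
    message(sum(bad), " malformed fix row(s) rejected (rows ",
            paste(head(which(bad), 5), collapse = ","),
            if (sum(bad) > 5) ", ..." else "", ")")
  ok <- data.frame(female_id = raw$female_id[!bad], t = t[!bad],
                   lon = lon[!bad], lat = lat[!bad], stringsAsFactors = FALSE)
  out <- lapply(split(ok, ok$female_id, drop = TRUE), as_trajectory)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write trajectories to a fix CSV
#'
#' @param trajectories a trajectory, list of trajectories, or `den_study`.
#' @param path output CSV path.
#' @param digits coordinate decimal places.
#' @export
write_fixes <- function(trajectories, path, digits = 6) {
  trajs <- as_trajectory_list(
    if (is.data.frame(trajectories)) list(trajectories) else trajectories)
  df <- do.call(rbind, lapply(trajs, function(tr) data.frame(
    female_id = tr$female_id,
    timestamp_iso8601 = format(tr$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lon = round(tr$lon, digits), lat = round(tr$lat, digits),
    stringsAsFactors = FALSE)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cluster centroids as GeoJSON points
#' @param clusters output of [detect_clusters()].
#' @param path output path (`.geojson`).
#' @export
write_clusters_geojson <- function(clusters, path) {
  feats <- lapply(seq_len(nrow(clusters)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(clusters$lon[i], clusters$lat[i])),
    properties = list(female_id = as.character(clusters$female_id[i]),
                      start = format(clusters$start_t[i], "%Y-%m-%dT%H:%M:%S"),
                      end = format(clusters$end_t[i], "%Y-%m-%dT%H:%M:%S"),
                      n_fixes = clusters$n_fixes[i],
                      duration_days = clusters$duration_days[i])))
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write monthly LoCoh isopleth polygons as GeoJSON
#'
#' Re-runs the isopleth construction for each usable month with hull
#' retention and exports the accumulated hull rings (inverse-projected to
#' WGS84) as MultiPolygon features.
#'
#' @param traj a trajectory.
#' @param path output path.
#' @param fractions isopleth levels.
#' @inheritParams monthly_ranges
#' @export
write_ranges_geojson <- function(traj, path, fractions = c(0.5, 0.9),
                                 k_rule = k_sqrt, tz_offset_h = 2) {
  traj <- as_trajectory(traj)
  mo <- civil_ym(traj$t, tz_offset_h)
  feats <- list()
  for (m in sort(unique(mo))) {
    sub <- traj[mo == m, , drop = FALSE]
    k <- k_rule(nrow(sub))
    if (nrow(sub) < k + 1) next
    xy <- project_local(sub$lon, sub$lat)
    iso <- suppressWarnings(locoh_isopleths(xy, k, fractions, keep_hulls = TRUE))
    hl <- attr(iso, "hulls")
    for (fi in seq_along(fractions)) {
      rings <- lapply(hl[[fi]], function(r) {
        if (nrow(r) < 3) return(NULL)
        ll <- local_unproject(rbind(r, r[1, ]), center = attr(xy, "center"))
        lapply(seq_len(nrow(ll)), function(j) c(ll[j, 1], ll[j, 2]))
      })
      rings <- Filter(Negate(is.null), rings)
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        geometry = list(type = "MultiPolygon",
                        coordinates = lapply(rings, list)),
        properties = list(female_id = as.character(traj$female_id[1]),
                          month = ym_format(m), fraction = fractions[fi],
                          area_km2 = iso$area_km2[fi]))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Either a simulation block (a [sim_config()] or its argument list) or
#' paths to input CSVs, plus detector settings. May be read from a YAML
#' file with `pipeline_config(yaml = path)`.
#'
#' @param sim a [sim_config()] or list of its arguments, or NULL.
#' @param fixes_csv path to a fix CSV (exclusive with `sim`).
#' @param env_csv optional environment-calendar CSV (needed for the
#'   association stage when `sim` is not used).
#' @param regions_csv optional CSV `female_id,region` (association stage).
#' @param out_dir output directory.
#' @param radius_m,min_fixes,gestation_months,wet_months,threshold detector
#'   settings, as in [parturition()].
#' @param seed seed echoed into the run log (and into `sim` if simulating).
#' @param yaml path to a YAML file supplying any of the above.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = NULL, fixes_csv = NULL, env_csv = NULL,
                            regions_csv = NULL, out_dir = "lionden-out",
                            radius_m = 200, min_fixes = 3,
                            gestation_months = 3, wet_months = c(10:12, 1:3),
                            threshold = 2, seed = 42, yaml = NULL) {
  cfg <- as.list(environment())
  cfg$yaml <- NULL
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  }
  if (is.null(cfg$sim) == is.null(cfg$fixes_csv))
    stop("supply exactly one of 'sim' or 'fixes_csv'")
  if (!is.null(cfg$sim) && !inherits(cfg$sim, "sim_config")) {
    cfg$sim$seed <- cfg$sim$seed %||% cfg$seed
    cfg$sim <- do.call(sim_config, cfg$sim)
  }
  if (!is.null(cfg$fixes_csv) && !file.exists(cfg$fixes_csv))
    stop("fixes_csv does not exist: ", cfg$fixes_csv)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Simulate (or read) fixes, detect residency clusters and monthly ranges,
#' score birth-month candidates, backdate conceptions, and (when an
#' environment calendar is available) run the seasonal association. Writes
#' `clusters.csv`, `monthly_ranges.csv`, `candidates.csv`, `calls.csv`,
#' `model_selection.csv`, `seasonal_tally.csv`, `clusters.geojson` and a
#' `run_log.txt` echoing the seed and configuration into `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the `parturition` fit and the
#'   `seasonal_assoc` result (NULL when no environment is available).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$out_dir, "run_log.txt")
  logline <- function(...) cat(..., "\n", file = log, append = TRUE, sep = " ")
  cat("lionden pipeline run\n", file = log)
  logline("seed:", config$seed)

  if (!is.null(config$sim)) {
    study <- simulate_study(config$sim)
    trajs <- study$trajectories
    env <- study$env
    regions <- setNames(study$truth$region, study$truth$female_id)
    write_fixes(trajs, file.path(config$out_dir, "fixes.csv"))
    write.csv(study$env, file.path(config$out_dir, "environment.csv"),
              row.names = FALSE)
    write.csv(study$truth, file.path(config$out_dir, "truth.csv"),
              row.names = FALSE)
    logline("simulated females:", length(trajs))
  } else {
    trajs <- read_fixes(config$fixes_csv)
    env <- if (!is.null(config$env_csv)) read.csv(config$env_csv) else NULL
    regions <- if (!is.null(config$regions_csv)) {
      rc <- read.csv(config$regions_csv, stringsAsFactors = FALSE)
      setNames(rc$region, rc$female_id)
    } else NULL
    logline("read females:", length(trajs),
            " rejected rows:", attr(trajs, "n_rejected"))
  }

  fit <- parturition(trajs, radius_m = config$radius_m,
                     min_fixes = config$min_fixes,
                     gestation_months = config$gestation_months,
                     wet_months = config$wet_months,
                     threshold = config$threshold)
  write.csv(fit$clusters, file.path(config$out_dir, "clusters.csv"),
            row.names = FALSE)
  write.csv(fit$ranges, file.path(config$out_dir, "monthly_ranges.csv"),
            row.names = FALSE)
  cand <- fit$candidates %||% data.frame()
  write.csv(cand, file.path(config$out_dir, "candidates.csv"), row.names = FALSE)
  write.csv(fit$calls %||% data.frame(), file.path(config$out_dir, "calls.csv"),
            row.names = FALSE)
  if (nrow(fit$clusters))
    write_clusters_geojson(fit$clusters, file.path(config$out_dir, "clusters.geojson"))
  logline("clusters:", nrow(fit$clusters), " candidates:", nrow(cand),
          " calls:", if (is.null(fit$calls)) 0 else nrow(fit$calls))

  assoc <- NULL
  if (!is.null(env) && !is.null(fit$calls) && nrow(fit$calls) > 0) {
    assoc <- seasonal_association(fit, env, regions = regions,
                                  wet_months = config$wet_months)
    write.csv(assoc$tally, file.path(config$out_dir, "seasonal_tally.csv"),
              row.names = FALSE)
    ms <- rbind(data.frame(response = "conception",
                           as.data.frame(assoc$models$conception)),
                data.frame(response = "birth",
                           as.data.frame(assoc$models$birth)))
    write.csv(ms, file.path(config$out_dir, "model_selection.csv"),
              row.names = FALSE)
    logline("association: wet conception fraction",
            paste(round(assoc$tally$conception_fraction_wet, 3), collapse = "/"))
  }
  logline("status: ok")
  invisible(list(fit = fit, association = assoc))
}

#' Model-selection table writer
#'
#' CSV with columns `model,k,AIC,AICc,delta,weight`.
#' @param tab an [akaike_table()].
#' @param path output CSV path.
#' @export
write_model_selection <- function(tab, path) {
  df <- data.frame(model = tab$name, k = tab$k, AIC = tab$AIC, AICc = tab$AICc,
                   delta = tab$delta, weight = tab$weight)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
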