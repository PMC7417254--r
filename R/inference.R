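# Birth-month inference: combine the monthly movement indicators into a
# weighted z-score per candidate month, rank candidates per female, backdate
# conception over the gestation period, and classify events by season and
# prey pulse.

#' Backdate a birth month to the conception month
#'
#' Shifts a calendar month back by the gestation period (default 3 months
#' for lions), with correct year rollover.
#'
#' @param birth_month `"YYYY-MM"`, Date, or month index.
#' @param gestation_months months to subtract.
#' @return conception month in the same representation as the input.
#' @examples
#' backdate_conception("2011-06") # "2011-03"
#' backdate_conception("2011-01") # "2010-10"
#' @export
backdate_conception <- function(birth_month, gestation_months = 3) {
  stopifnot(gestation_months >= 0)
  out <- ym_parse(birth_month) - as.integer(gestation_months)
  if (is.numeric(birth_month)) out else ym_format(out)
}

#' Advance a conception month to the birth month
#'
#' Exact inverse of [backdate_conception()].
#' @inheritParams backdate_conception
#' @param conception_month `"YYYY-MM"`, Date, or month index.
#' @export
advance_conception <- function(conception_month, gestation_months = 3) {
  stopifnot(gestation_months >= 0)
  out <- ym_parse(conception_month) + as.integer(gestation_months)
  if (is.numeric(conception_month)) out else ym_format(out)
}

#' Season of a calendar month
#'
#' Wet season is October through March by default (the months carrying
#' ~80% of annual rainfall in the study system); everything else is dry.
#'
#' @param month `"YYYY-MM"`, Date, month index, or a bare calendar month
#'   number 1-12.
#' @param wet_months calendar months belonging to the wet season.
#' @return `"wet"` or `"dry"` (vectorized).
#' @examples
#' season_of("2011-10") # wet
#' season_of(4)         # dry
#' @export
season_of <- function(month, wet_months = c(10:12, 1:3)) {
  mo <- if (is.numeric(month) && all(month >= 1 & month <= 12)) {
    as.integer(month)
  } else {
    ym_month(ym_parse(month))
  }
  ifelse(mo %in% wet_months, "wet", "dry")
}

#' Default indicator weights
#'
#' Weights for the three birth-month indicators, proportional to the Akaike
#' weights of the corresponding candidate models in the denning-site model
#' selection: the 50% core-range model (0.74456) for core contraction, the
#' two step-length models combined (0.00025 + 0.00016) for displacement
#' reduction, and the remaining localized-use model, 90% total range
#' (0.10593), as the proxy for residency duration, for which no candidate
#' model was fit. Renormalized to sum to 1.
#' @return named numeric vector `core`, `disp`, `residency`.
#' @export
default_indicator_weights <- function() {
  w <- c(core = 0.74456, disp = 0.00025 + 0.00016, residency = 0.10593)
  w / sum(w)
}

#' Score candidate birth months for one female
#'
#' Each month's score is a weighted sum of z-scores computed against the
#' female's own months: `w_core * z(-log core50) + w_disp * z(-dnd) +
#' w_res * z(residency)`. A denning month shows up as a simultaneous core
#' contraction, displacement drop and long residency, so it scores high.
#' Months are ranked by score; ties break to the earlier month.
#'
#' @param metrics data.frame with columns `month` (`"YYYY-MM"`), `dnd_km`
#'   (mean daily net displacement), `core50_km2`, `residency_days` (longest
#'   cluster overlapping the month; 0 if none). Months with `NA` metrics are
#'   dropped.
#' @param weights named weights (`core`, `disp`, `residency`); default
#'   [default_indicator_weights()].
#' @param gestation_months for conception backdating.
#' @param threshold call threshold in score (z) units.
#' @param min_baseline_months minimum usable months (a baseline is needed
#'   for the z-scores).
#' @return data.frame of ranked candidates: `birth_month`,
#'   `conception_month`, `score`, `called`, and the per-month indicators
#'   `displacement_reduction_frac`, `core_contraction_ratio`,
#'   `max_residency_days`.
#' @export
score_birth_months <- function(metrics, weights = default_indicator_weights(),
                               gestation_months = 3, threshold = 2,
                               min_baseline_months = 3) {
  need <- c("month", "dnd_km", "core50_km2", "residency_days")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("metrics missing columns: ", paste(miss, collapse = ", "))
  m <- metrics[stats::complete.cases(metrics[need]), need, drop = FALSE]
  if (nrow(m) < min_baseline_months)
    stop("insufficient baseline: need at least ", min_baseline_months,
         " months of complete metrics, have ", nrow(m))
  w <- weights[c("core", "disp", "residency")]
  stopifnot(!anyNA(w), all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  core_floor <- pmax(m$core50_km2, 1e-6)
  score <- w[["core"]] * zs(-log(core_floor)) +
    w[["disp"]] * zs(-m$dnd_km) +
    w[["residency"]] * zs(m$residency_days)
  med_other <- function(v) vapply(seq_along(v), function(i) median(v[-i]), 0)
  med_dnd <- med_other(m$dnd_km)
  med_core <- med_other(core_floor)
  out <- data.frame(
    birth_month = m$month,
    conception_month = vapply(m$month, backdate_conception, "",
                              gestation_months = gestation_months),
    score = score,
    called = score > threshold,
    displacement_reduction_frac = ifelse(med_dnd > 0, 1 - m$dnd_km / med_dnd, NA),
    core_contraction_ratio = core_floor / pmax(med_core, 1e-12),
    max_residency_days = m$residency_days,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, ym_parse(out$birth_month)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Detect parturition events from collar telemetry
#'
#' The package's central fit. For every female it computes the monthly
#' movement indicators (mean daily net displacement, 50% core LoCoh range,
#' longest residency-cluster duration), scores each month with
#' [score_birth_months()], and returns the ranked birth-month candidates
#' with backdated conception months and wet/dry season labels.
#'
#' @param fixes a `den_study` from [simulate_study()], a list of
#'   trajectories, or a single fix data.frame with a `female_id` column
#'   (several females allowed).
#' @param radius_m residency radius (m) for cluster detection.
#' @param min_fixes minimum fixes per kept cluster.
#' @param gestation_months gestation for conception backdating.
#' @param wet_months calendar months of the wet season.
#' @param weights indicator weights, see [default_indicator_weights()].
#' @param threshold call threshold (score units) above which a month is
#'   declared a birth month.
#' @param k_rule LoCoh neighbour rule, a function of the monthly fix count.
#' @param tz_offset_h civil day/month boundary offset (hours from UTC).
#' @param min_baseline_months minimum complete months per female; females
#'   with less are reported in `$skipped` rather than failing the fit.
#' @return object of class `"parturition"` with elements `metrics`
#'   (female-month indicator table), `candidates` (all scored months),
#'   `calls` (top candidate per female when above threshold), `clusters`,
#'   `ranges`, `skipped`, `config`.
#' @export
parturition <- function(fixes, radius_m = 200, min_fixes = 3,
                        gestation_months = 3, wet_months = c(10:12, 1:3),
                        weights = default_indicator_weights(), threshold = 2,
                        k_rule = k_sqrt, tz_offset_h = 2,
                        min_baseline_months = 3) {
  trajs <- as_trajectory_list(fixes)
  metrics_l <- list(); cand_l <- list(); clus_l <- list(); rng_l <- list()
  skipped <- character()
  for (id in names(trajs)) {
    traj <- trajs[[id]]
    cl <- detect_clusters(traj, radius_m = radius_m, min_fixes = min_fixes)
    rng <- monthly_ranges(traj, k_rule = k_rule, tz_offset_h = tz_offset_h)
    dnd <- daily_net_displacement(traj, tz_offset_h = tz_offset_h)
    dnd_ym <- civil_ym(as.POSIXct(dnd$day, tz = "UTC"), 0)
    mdnd <- if (nrow(dnd)) {
      agg <- aggregate(dnd$dnd_km, by = list(ymi = dnd_ym), FUN = mean)
      setNames(agg$x, ym_format(agg$ymi))
    } else numeric()
    res_days <- vapply(rng$month, function(mlab) {
      s <- duration_of_stay(cl, mlab, tz_offset_h = tz_offset_h)
      if (s$n == 0) 0 else s$max_days
    }, 0)
    met <- data.frame(
      female_id = id, month = rng$month, n_fixes = rng$n_fixes,
      dnd_km = unname(mdnd[rng$month]),
      core50_km2 = rng$core50_km2, total90_km2 = rng$total90_km2,
      residency_days = res_days, stringsAsFactors = FALSE
    )
    metrics_l[[id]] <- met
    clus_l[[id]] <- cl
    rng_l[[id]] <- rng
    cand <- tryCatch(
      score_birth_months(met, weights = weights,
                         gestation_months = gestation_months,
                         threshold = threshold,
                         min_baseline_months = min_baseline_months),
      error = function(e) e)
    if (inherits(cand, "error")) { skipped <- c(skipped, id); next }
    cand <- data.frame(female_id = id, cand, stringsAsFactors = FALSE)
    cand$conception_season <- season_of(cand$conception_month, wet_months)
    cand$birth_season <- season_of(cand$birth_month, wet_months)
    cand_l[[id]] <- cand
  }
  candidates <- if (length(cand_l)) do.call(rbind, cand_l) else NULL
  calls <- NULL
  if (!is.null(candidates)) {
    top <- candidates[candidates$rank == 1 & candidates$called, , drop = FALSE]
    rownames(top) <- NULL
    calls <- top
  }
  structure(list(
    metrics = do.call(rbind, metrics_l),
    candidates = candidates,
    calls = calls,
    clusters = do.call(rbind, clus_l),
    ranges = do.call(rbind, rng_l),
    skipped = skipped,
    config = list(radius_m = radius_m, min_fixes = min_fixes,
                  gestation_months = gestation_months,
                  wet_months = wet_months, weights = weights,
                  threshold = threshold, tz_offset_h = tz_offset_h)
  ), class = "parturition")
}

# normalize the accepted input forms to a named list of trajectories
as_trajectory_list <- function(fixes) {
  if (inherits(fixes, "den_study")) return(fixes$trajectories)
  if (is.data.frame(fixes)) {
    sp <- split(fixes, fixes$female_id, drop = TRUE)
    return(lapply(sp, as_trajectory))
  }
  if (is.list(fixes)) {
    trajs <- lapply(fixes, as_trajectory)
    names(trajs) <- vapply(trajs, function(x) as.character(x$female_id[1]), "")
    return(trajs)
  }
  stop("cannot interpret 'fixes' as trajectories")
}

#' @export
print.parturition <- function(x, ...) {
  nf <- length(unique(x$metrics$female_id))
  cat("Parturition detection fit:", nf, "females,",
      nrow(x$metrics), "female-months\n")
  cat("  birth calls (score >", x$config$threshold, "):",
      if (is.null(x$calls)) 0 else nrow(x$calls), "\n")
  if (length(x$skipped))
    cat("  skipped (insufficient baseline):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.parturition <- function(object, ...) {
  top <- object$candidates[object$candidates$rank == 1, , drop = FALSE]
  tab <- top[, c("female_id", "birth_month", "conception_month", "score",
                 "called", "conception_season")]
  rownames(tab) <- NULL
  wet <- sum(top$called & top$conception_season == "wet")
  dry <- sum(top$called & top$conception_season == "dry")
  out <- list(top = tab, n_calls = wet + dry,
              conception_wet_fraction = if (wet + dry) wet / (wet + dry) else NA_real_,
              threshold = object$config$threshold)
  class(out) <- "summary.parturition"
  out
}

#' @export
print.summary.parturition <- function(x, ...) {
  cat("Top-ranked birth-month candidate per female:\n")
  y <- x$top
  y$score <- round(y$score, 2)
  print(y, row.names = FALSE)
  cat("\nBirth calls:", x$n_calls,
      " wet-season conception fraction among calls:",
      if (is.na(x$conception_wet_fraction)) "NA"
      else sprintf("%.2f", x$conception_wet_fraction), "\n")
  invisible(x)
}

#' @export
plot.parturition <- function(x, female = NULL, ...) {
  ids <- unique(x$candidates$female_id)
  if (is.null(ids)) stop("no scored females to plot")
  female <- female %||% ids[1]
  cc <- x$candidates[x$candidates$female_id == female, ]
  cc <- cc[order(ym_parse(cc$birth_month)), ]
  graphics::plot(ym_parse(cc$birth_month) - min(ym_parse(cc$birth_month)) + 1,
                 cc$score, type = "h", lwd = 3,
                 xlab = paste0("month (from ", cc$birth_month[1], ")"),
                 ylab = "birth-month score",
                 main = paste("Female", female), ...)
  graphics::abline(h = x$config$threshold, lty = 2, col = "red3")
  invisible(x)
}

#' Seasonal and prey-pulse association of detected events
#'
#' Builds the female-month 0/1 outcome series (1 in the event month, 0
#' elsewhere) for conceptions and births, tallies events by wet/dry season
#' per region, and fits the candidate binomial GLMs (logit link; the 0/1
#' response matches the event coding) with season and prey-pulse predictors,
#' summarized in an AICc model-selection table.
#'
#' @param candidates a `"parturition"` fit (its calls are used; all top
#'   candidates when no call passes the threshold), or a data.frame with
#'   `female_id`, `birth_month`, `conception_month`.
#' @param env environmental calendar as from [simulate_environment()]
#'   (columns `region`, `month_label`, `prey_pulse`, `season`). It must
#'   cover every candidate birth month; a conception backdated to before
#'   the calendar contributes no event to the female-month series (the
#'   seasonal tally still classifies it by calendar month).
#' @param regions named character vector mapping `female_id` to region;
#'   defaults to the single region in `env` when unambiguous.
#' @param wet_months wet-season calendar months for the tally.
#' @return list of class `"seasonal_assoc"`: `tally` (per-region wet/dry
#'   counts and fractions for conceptions and births), `models` (an
#'   [akaike_table()] over the candidate GLMs for each response), `data`
#'   (the female-month table), `separation` flags.
#' @export
seasonal_association <- function(candidates, env, regions = NULL,
                                 wet_months = c(10:12, 1:3)) {
  if (inherits(candidates, "parturition")) {
    cand <- candidates$calls
    if (is.null(cand) || nrow(cand) == 0)
      cand <- candidates$candidates[candidates$candidates$rank == 1, , drop = FALSE]
  } else cand <- candidates
  if (is.null(cand) || nrow(cand) == 0) stop("no candidates supplied")
  need <- c("female_id", "birth_month", "conception_month")
  miss <- setdiff(need, names(cand))
  if (length(miss)) stop("candidates missing columns: ", paste(miss, collapse = ", "))
  if (is.null(regions)) {
    if (!is.null(cand$region)) {
      regions <- setNames(cand$region, cand$female_id)
    } else if (length(unique(env$region)) == 1) {
      regions <- setNames(rep(env$region[1], nrow(cand)), cand$female_id)
    } else stop("supply 'regions' (female_id -> region) with a multi-region env")
  }
  # female-month outcome table over each female's regional calendar
  fm <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
    reg <- regions[[as.character(cand$female_id[i])]]
    e <- env[env$region == reg, , drop = FALSE]
    if (!cand$birth_month[i] %in% e$month_label)
      stop("environment calendar does not cover the birth month for female ",
           cand$female_id[i])
    # a conception backdated to before the calendar starts is simply not
    # observed in the female-month series (the tally classifies it by
    # calendar month regardless)
    data.frame(female_id = cand$female_id[i], region = reg,
               month_label = e$month_label,
               season_wet = as.integer(e$season == "wet"),
               prey_pulse = as.integer(e$prey_pulse),
               conception = as.integer(e$month_label == cand$conception_month[i]),
               birth = as.integer(e$month_label == cand$birth_month[i]),
               stringsAsFactors = FALSE)
  }))
  tally <- do.call(rbind, lapply(unique(fm$region), function(reg) {
    cw <- sum(cand$female_id %in% names(regions)[regions == reg] &
                season_of(cand$conception_month, wet_months) == "wet" &
                vapply(cand$female_id, function(f) regions[[as.character(f)]], "") == reg)
    sub <- cand[vapply(cand$female_id, function(f) regions[[as.character(f)]], "") == reg, ]
    conc_wet <- sum(season_of(sub$conception_month, wet_months) == "wet")
    birth_wet <- sum(season_of(sub$birth_month, wet_months) == "wet")
    n <- nrow(sub)
    data.frame(region = reg,
               n_conceptions_wet = conc_wet, n_conceptions_dry = n - conc_wet,
               conception_fraction_wet = conc_wet / n,
               n_births_wet = birth_wet, n_births_dry = n - birth_wet,
               birth_fraction_wet = birth_wet / n,
               stringsAsFactors = FALSE)
  }))
  fit_set <- function(y) {
    X0 <- cbind(intercept = rep(1, nrow(fm)))
    designs <- list(
      "intercept" = X0,
      "season" = cbind(X0, season = fm$season_wet),
      "prey pulse" = cbind(X0, prey = fm$prey_pulse),
      "season + prey pulse" = cbind(X0, season = fm$season_wet, prey = fm$prey_pulse)
    )
    fits <- lapply(designs, function(X) fit_binary_glm(y, X))
    tab <- akaike_table(data.frame(
      name = names(fits),
      k = vapply(fits, `[[`, 0, "k"),
      loglik = vapply(fits, `[[`, 0, "loglik"),
      n = nrow(fm)))
    list(table = tab, separation = vapply(fits, `[[`, TRUE, "separation"))
  }
  conc <- fit_set(fm$conception)
  birt <- fit_set(fm$birth)
  structure(list(tally = tally,
                 models = list(conception = conc$table, birth = birt$table),
                 separation = list(conception = conc$separation,
                                   birth = birt$separation),
                 data = fm),
            class = "seasonal_assoc")
}

#' @export
print.seasonal_assoc <- function(x, ...) {
  cat("Seasonal tally of detected events:\n")
  print(x$tally, row.names = FALSE)
  cat("\nConception models:\n"); print(x$models$conception)
  cat("\nBirth models:\n"); print(x$models$birth)
  if (any(unlist(x$separation)))
    cat("note: separation detected in some fits (ridge-stabilized)\n")
  invisible(x)
}
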