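# Independent brute-force oracles used to cross-check the package's
# implementations. Everything here is written from the definitions, not by
# calling back into the code under test.

# "YYYY-MM" -> integer month index (independent of the package's internals)
month_index <- function(s) {
  y <- as.integer(substr(s, 1, 4))
  m <- as.integer(substr(s, 6, 7))
  12L * y + m - 1L
}

# civil-month label (UTC+2) of POSIXct timestamps
civil_month_label <- function(t, tz_offset_h = 2) {
  format(t + tz_offset_h * 3600, "%Y-%m", tz = "UTC")
}

# Exhaustive greedy residency-cluster scan, re-derived from the definition:
# walk the fixes once; a fix joins the open cluster iff its great-circle
# distance to the running centroid (plain lon/lat mean) is <= radius_m,
# otherwise the cluster closes (kept iff >= min_fixes) and reopens there.
oracle_clusters <- function(lon, lat, radius_m, min_fixes) {
  n <- length(lon)
  out <- list()
  if (n == 0) return(out)
  start <- 1L
  members <- 1L
  repeat {
    nxt <- start + length(members)
    if (nxt > n) {
      if (length(members) >= min_fixes) out[[length(out) + 1L]] <- members
      break
    }
    cx <- mean(lon[members]); cy <- mean(lat[members])
    d <- lionden::haversine_km(cx, cy, lon[nxt], lat[nxt]) * 1000
    if (d <= radius_m) {
      members <- c(members, nxt)
    } else {
      if (length(members) >= min_fixes) out[[length(out) + 1L]] <- members
      start <- nxt
      members <- nxt
    }
  }
  out
}

# random short trajectory mixing tight dwelling and long moves, for the
# cluster oracle comparison
random_trajectory <- function(n, seed) {
  set.seed(seed)
  lon <- numeric(n); lat <- numeric(n)
  lon[1] <- 31 + runif(1, -0.5, 0.5)
  lat[1] <- -24 + runif(1, -0.5, 0.5)
  for (i in seq_len(n - 1)) {
    step_m <- if (runif(1) < 0.55) runif(1, 0, 260) else runif(1, 300, 5000)
    th <- runif(1, 0, 2 * pi)
    lat[i + 1] <- lat[i] + step_m * cos(th) / 111320
    lon[i + 1] <- lon[i] + step_m * sin(th) / (111320 * cos(lat[i] * pi / 180))
  }
  t0 <- as.POSIXct("2012-03-01 00:00:00", tz = "UTC")
  data.frame(female_id = "X01", t = t0 + (seq_len(n) - 1) * 14400,
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}

# Sutherland-Hodgman clipping of a (possibly non-convex ordered) subject
# polygon against a convex CCW clip polygon; rings are n x 2, open.
clip_convex <- function(subject, clip) {
  outp <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(outp) || nrow(outp) == 0) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    inp <- outp
    outp <- matrix(numeric(0), ncol = 2)
    np <- nrow(inp)
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    for (j in seq_len(np)) {
      p <- inp[j, ]; q <- inp[if (j == np) 1 else j + 1, ]
      sp <- side(p); sq <- side(q)
      if (sp >= 0) outp <- rbind(outp, p)
      if ((sp >= 0) != (sq >= 0)) {
        t <- sp / (sp - sq)
        outp <- rbind(outp, p + t * (q - p))
      }
    }
  }
  if (nrow(outp) < 3) NULL else outp
}

polygon_area <- function(ring) {
  if (is.null(ring) || nrow(ring) < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Exact union area of up to three convex polygons by inclusion-exclusion,
# with all intersections computed by Sutherland-Hodgman clipping.
union_area_incl_excl <- function(hulls) {
  k <- length(hulls)
  stopifnot(k >= 1, k <= 3)
  total <- sum(vapply(hulls, polygon_area, 0))
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      total <- total - polygon_area(clip_convex(hulls[[i]], hulls[[j]]))
  }
  if (k == 3) {
    i12 <- clip_convex(hulls[[1]], hulls[[2]])
    if (!is.null(i12)) total <- total + polygon_area(clip_convex(i12, hulls[[3]]))
  }
  total
}

# counterclockwise convex hull ring of a point matrix (open ring)
ccw_hull <- function(xy) {
  idx <- grDevices::chull(xy)
  ring <- xy[idx, , drop = FALSE]
  x <- ring[, 1]; y <- ring[, 2]
  if (nrow(ring) >= 3 &&
      sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2 < 0)
    ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  ring
}

# direct textbook logistic log-likelihood for a coefficient vector
logistic_loglik <- function(beta, y, X) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# memoised default-study cache shared across acceptance blocks
.study_cache <- new.env(parent = emptyenv())
cached_study <- function(seed) {
  key <- as.character(seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- lionden::simulate_study(lionden::sim_config(seed = seed))
  .study_cache[[key]]
}
cached_fit <- function(seed) {
  key <- paste0("fit", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- lionden::parturition(cached_study(seed))
  .study_cache[[key]]
}
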