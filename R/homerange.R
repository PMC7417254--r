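# Monthly 50% core / 90% total ranges via k-LoCoh (local convex hulls), with
# a minimum convex polygon as an independent cross-check. All geometry is
# done in a local azimuthal-equidistant plane (km) about the point centroid;
# no external geometry engine is used because none that provides LoCoh is
# a dependency of this package, and the primitives (convex hulls, polygon
# union areas) are small and exactly testable.

#' Project lon/lat to a local planar frame (km)
#'
#' Azimuthal equidistant projection on the sphere (R = 6371.0088 km) about
#' `center` (default: the coordinate mean). Distances from the center are
#' preserved exactly; areas are preserved to first order at home-range scale
#' (tens of km).
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param center optional `c(lon, lat)` projection center.
#' @return an `n x 2` matrix of x/y in km, with the center stored in
#'   `attr(, "center")` for inversion via [local_unproject()].
#' @export
project_local <- function(lon, lat, center = NULL) {
  if (length(lon) == 0) stop("no points to project")
  R <- 6371.0088
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  d2r <- pi / 180
  l0 <- center[1] * d2r; p0 <- center[2] * d2r
  l <- lon * d2r; p <- lat * d2r
  cosc <- sin(p0) * sin(p) + cos(p0) * cos(p) * cos(l - l0)
  cosc <- pmin(1, pmax(-1, cosc))
  cc <- acos(cosc)
  kp <- ifelse(cc < 1e-12, 1, cc / sin(cc))
  x <- R * kp * cos(p) * sin(l - l0)
  y <- R * kp * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(l - l0))
  out <- cbind(x = x, y = y)
  attr(out, "center") <- center
  out
}

#' Inverse of [project_local()]
#' @param xy `n x 2` matrix of planar km coordinates.
#' @param center `c(lon, lat)` projection center (taken from `xy`'s
#'   attribute when present).
#' @return matrix with columns `lon`, `lat` in degrees.
#' @export
local_unproject <- function(xy, center = attr(xy, "center")) {
  if (is.null(center)) stop("projection center unknown")
  R <- 6371.0088
  d2r <- pi / 180
  l0 <- center[1] * d2r; p0 <- center[2] * d2r
  x <- xy[, 1]; y <- xy[, 2]
  rho <- sqrt(x^2 + y^2)
  cc <- rho / R
  phi <- ifelse(rho < 1e-12, p0,
                asin(cos(cc) * sin(p0) + y * sin(cc) * cos(p0) / pmax(rho, 1e-300)))
  lam <- ifelse(rho < 1e-12, l0,
                l0 + atan2(x * sin(cc),
                           rho * cos(p0) * cos(cc) - y * sin(p0) * sin(cc)))
  cbind(lon = lam / d2r, lat = phi / d2r)
}

# ---- planar polygon primitives -------------------------------------------

# signed shoelace area; ring is an n x 2 matrix, first vertex not repeated
shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# counterclockwise convex hull ring of a point set (may be a segment/point)
hull_ring <- function(xy) {
  idx <- grDevices::chull(xy)
  ring <- xy[idx, , drop = FALSE]
  if (nrow(ring) >= 3 && shoelace(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  ring
}

# which of pts lie inside/on a convex CCW ring (eps-inclusive); degenerate
# rings (point/segment) cover points within eps of themselves
points_in_hull <- function(pts, ring, eps = 1e-9) {
  n <- nrow(ring)
  if (n == 1) {
    return(sqrt((pts[, 1] - ring[1, 1])^2 + (pts[, 2] - ring[1, 2])^2) <= eps)
  }
  if (n == 2) {
    return(point_seg_dist(pts, ring[1, ], ring[2, ]) <= eps)
  }
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (ring[j, 1] - ring[i, 1]) * (pts[, 2] - ring[i, 2]) -
          (ring[j, 2] - ring[i, 2]) * (pts[, 1] - ring[i, 1])
    inside <- inside & cr >= -eps
    if (!any(inside)) break
  }
  inside
}

point_seg_dist <- function(pts, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  L2 <- abx^2 + aby^2
  if (L2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- pmin(1, pmax(0, ((pts[, 1] - a[1]) * abx + (pts[, 2] - a[2]) * aby) / L2))
  px <- a[1] + t * abx; py <- a[2] + t * aby
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

#' Area of a union of convex polygons
#'
#' Exact (to floating point) union area via a vertical slab decomposition:
#' slab boundaries are all vertex x-coordinates plus all pairwise edge
#' intersections, so within a slab the covered y-length is linear in x and
#' the midpoint rule integrates it exactly. Spatially disjoint groups of
#' hulls (by bounding-box overlap) are handled independently, exact
#' duplicate hulls are collapsed, and hulls wholly contained in a retained
#' hull are pruned first.
#'
#' @param hulls list of convex rings (`n x 2` matrices). Degenerate rings
#'   (fewer than 3 vertices, or zero area) contribute nothing.
#' @return total union area (same squared units as the input coordinates).
#' @export
convex_union_area <- function(hulls) {
  hulls <- Filter(function(h) nrow(h) >= 3 && abs(shoelace(h)) > 0, hulls)
  if (length(hulls) == 0) return(0)
  key <- vapply(hulls, function(h) {
    i <- order(h[, 1], h[, 2])[1]
    idx <- c(seq_len(nrow(h)), seq_len(nrow(h)))[i:(i + nrow(h) - 1)]
    paste(h[idx, ], collapse = ",")
  }, "")
  hulls <- hulls[!duplicated(key)]
  bb <- t(vapply(hulls, function(h) c(min(h[, 1]), max(h[, 1]),
                                      min(h[, 2]), max(h[, 2])), numeric(4)))
  comp <- bbox_components(bb)
  total <- 0
  for (cid in unique(comp)) {
    hs <- hulls[comp == cid]
    if (length(hs) == 1) { total <- total + abs(shoelace(hs[[1]])); next }
    hs <- prune_contained(hs)
    if (length(hs) == 1) { total <- total + abs(shoelace(hs[[1]])); next }
    total <- total + union_area_sweep(hs)
  }
  total
}

# connected components of the bbox-overlap graph (conservative grouping:
# disjoint bboxes imply disjoint polygons, so component areas add exactly)
bbox_components <- function(bb) {
  n <- nrow(bb)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      ov <- bb[, 1] <= bb[i, 2] & bb[, 2] >= bb[i, 1] &
            bb[, 3] <= bb[i, 4] & bb[, 4] >= bb[i, 3]
      m <- min(comp[ov])
      if (any(comp[ov] != m)) { comp[ov] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  comp
}

prune_contained <- function(hs) {
  areas <- vapply(hs, function(h) abs(shoelace(h)), 0)
  hs <- hs[order(-areas)]
  hs[.prune_contained(hs, 1e-12)]
}

union_area_sweep <- function(hs) .union_area_sweep(hs)

#' Minimum convex polygon area
#'
#' Convex-hull area of the `fraction` of points closest to the point
#' centroid; the standard MCP estimator, used here mainly as an independent
#' oracle for LoCoh at fraction 1.
#'
#' @param xy `n x 2` matrix of planar points (km).
#' @param fraction fraction of points (closest to centroid) to keep.
#' @return hull area (km^2); 0 with a warning for degenerate (collinear)
#'   geometry.
#' @export
mcp_area <- function(xy, fraction = 1.0) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) stop("need at least 3 points")
  stopifnot(fraction > 0, fraction <= 1)
  ctr <- colMeans(xy)
  d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  keep <- order(d)[seq_len(max(3, ceiling(fraction * nrow(xy))))]
  ring <- hull_ring(xy[keep, , drop = FALSE])
  if (nrow(ring) < 3) {
    warning("degenerate (collinear) point set: zero MCP area")
    return(0)
  }
  abs(shoelace(ring))
}

#' k-LoCoh isopleth areas
#'
#' Local convex hull home-range estimator: for every point, the convex hull
#' of the point and its `k` nearest neighbours (ties broken by point index)
#' is built; hulls are sorted by ascending area (ties by parent point index)
#' and their union accumulated until it covers at least `fraction * n`
#' points (a point counts as covered when inside or on the boundary of the
#' running union; degenerate zero-area hulls still cover their points). The
#' isopleth area is the union area at that stopping point.
#'
#' @param xy `n x 2` matrix of planar points (km), e.g. from
#'   [project_local()].
#' @param k neighbours per hull; needs `n >= k + 1` and `k >= 2`.
#' @param fractions isopleth levels, in (0, 1].
#' @param keep_hulls if TRUE, attach the accumulated rings per fraction as
#'   attribute `"hulls"` (for polygon export).
#' @return data.frame `fraction`, `area_km2`, `n_hulls`, `n_covered`, sorted
#'   by fraction; attribute `"degenerate"` flags an all-collinear input.
#' @export
locoh_isopleths <- function(xy, k, fractions = c(0.5, 0.9), keep_hulls = FALSE) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (k < 2) stop("k must be at least 2")
  if (n < k + 1) stop("need at least k + 1 points")
  stopifnot(all(fractions > 0), all(fractions <= 1))
  fractions <- sort(fractions)
  # k nearest neighbours by planar distance, ties by index
  D <- as.matrix(stats::dist(xy))
  hulls <- vector("list", n)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ], seq_len(n))[seq_len(k + 1)] # includes i itself (d=0)
    if (!(i %in% nb)) nb[k + 1] <- i
    ring <- hull_ring(xy[nb, , drop = FALSE])
    hulls[[i]] <- ring
    areas[i] <- if (nrow(ring) >= 3) abs(shoelace(ring)) else 0
  }
  ord <- order(areas, seq_len(n))
  ncov <- .cover_counts(hulls[ord], xy, 1e-9)
  out <- data.frame(fraction = fractions, area_km2 = NA_real_,
                    n_hulls = NA_integer_, n_covered = NA_integer_)
  kept <- if (keep_hulls) vector("list", length(fractions)) else NULL
  for (fi in seq_along(fractions)) {
    need <- fractions[fi] * n - 1e-9
    m <- which(ncov >= need)[1]
    if (is.na(m)) m <- n # safety net; full set always covers all points
    sel <- hulls[ord[seq_len(m)]]
    out$area_km2[fi] <- convex_union_area(sel)
    out$n_hulls[fi] <- m
    out$n_covered[fi] <- ncov[m]
    if (keep_hulls) kept[[fi]] <- sel
  }
  if (all(areas == 0)) {
    attr(out, "degenerate") <- TRUE
    warning("all local hulls degenerate (collinear points): zero areas")
  }
  if (keep_hulls) attr(out, "hulls") <- stats::setNames(kept, fractions)
  out
}

#' Default LoCoh neighbour rule
#'
#' `k = ceiling(sqrt(n))`, the square-root heuristic commonly used to pick
#' the LoCoh neighbourhood size.
#' @param n number of points.
#' @export
k_sqrt <- function(n) max(2L, as.integer(ceiling(sqrt(n))))

#' Monthly 50% core and 90% total LoCoh ranges
#'
#' Splits a trajectory into calendar months (civil time, default UTC+2) and
#' estimates the LoCoh isopleth areas per month. Months with fewer than
#' `k + 1` fixes are reported with `NA` areas (`ok = FALSE`).
#'
#' @param traj a trajectory.
#' @param k_rule function of the monthly fix count returning `k`
#'   (default [k_sqrt()]).
#' @param fractions isopleth levels (default core 0.5 and total 0.9).
#' @param tz_offset_h civil day/month boundary offset.
#' @param min_points months with fewer fixes than this are skipped outright.
#' @return data.frame of class `"monthly_ranges"`: `female_id`, `month`
#'   (`"YYYY-MM"`), `n_fixes`, `k`, `core50_km2`, `total90_km2`, `ok`.
#' @export
monthly_ranges <- function(traj, k_rule = k_sqrt, fractions = c(0.5, 0.9),
                           tz_offset_h = 2, min_points = 5) {
  traj <- as_trajectory(traj)
  mo <- civil_ym(traj$t, tz_offset_h)
  months <- sort(unique(mo))
  rows <- lapply(months, function(m) {
    sub <- traj[mo == m, , drop = FALSE]
    n <- nrow(sub)
    k <- k_rule(n)
    if (n < max(min_points, k + 1)) {
      return(data.frame(female_id = traj$female_id[1], month = ym_format(m),
                        n_fixes = n, k = NA_integer_, core50_km2 = NA_real_,
                        total90_km2 = NA_real_, ok = FALSE))
    }
    xy <- project_local(sub$lon, sub$lat)
    iso <- suppressWarnings(locoh_isopleths(xy, k, fractions))
    data.frame(female_id = traj$female_id[1], month = ym_format(m),
               n_fixes = n, k = as.integer(k),
               core50_km2 = iso$area_km2[match(0.5, iso$fraction)],
               total90_km2 = iso$area_km2[match(0.9, iso$fraction)],
               ok = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("monthly_ranges", "data.frame")
  out
}
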