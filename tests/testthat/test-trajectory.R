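t0 <- as.POSIXct("2011-05-01 00:00:00", tz = "UTC")

make_traj <- function(lon, lat, dt_h = 4) {
  data.frame(female_id = "F01", t = t0 + (seq_along(lon) - 1) * dt_h * 3600,
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}

test_that("haversine distance: closed form, symmetry, triangle inequality", {
  expect_equal(haversine_km(31, -24, 31, -24), 0)
  # 0.01 degree of latitude on a sphere of radius 6371.0088 km
  expect_equal(haversine_km(0, 0, 0, 0.01), 6371.0088 * 0.01 * pi / 180,
               tolerance = 1e-9)
  expect_equal(haversine_km(0, 0, 0, 0.01), 1.1119, tolerance = 1e-4)
  set.seed(11)
  for (r in 1:25) {
    p <- matrix(c(runif(3, -180, 180), runif(3, -89, 89)), ncol = 2)
    dab <- haversine_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    dba <- haversine_km(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    dac <- haversine_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    dcb <- haversine_km(p[3, 1], p[3, 2], p[2, 1], p[2, 2])
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("as_trajectory validates and orders fixes", {
  tr <- make_traj(c(31, 31.01, 31.02), c(-24, -24, -24))
  shuffled <- tr[c(3, 1, 2), ]
  out <- as_trajectory(shuffled)
  expect_s3_class(out, "trajectory")
  expect_identical(out$lon, tr$lon)
  bad <- tr; bad$lat[2] <- 95
  expect_error(as_trajectory(bad), "out-of-range")
  dup <- tr; dup$t[2] <- dup$t[1]
  expect_error(as_trajectory(dup), "duplicate")
  two <- rbind(tr, transform(tr, female_id = "F02", t = t + 1))
  expect_error(as_trajectory(two), "single female")
})

test_that("step_lengths: counts, zeros, empty input", {
  tr <- make_traj(c(31, 31, 31.1), c(-24, -24, -24))
  st <- step_lengths(tr)
  expect_equal(nrow(st), 2)
  expect_equal(st$dist_km[1], 0)
  expect_gt(st$dist_km[2], 0)
  expect_equal(nrow(step_lengths(tr[1, ])), 0)
})

test_that("daily net displacement averages steps within the civil day", {
  # four fixes at civil times 02,06,10,14 on one day; steps 1,2,3 km north
  d2deg <- function(km) km / (6371.0088 * pi / 180)
  lat <- -24 + d2deg(cumsum(c(0, 1, 2, 3)))
  tr <- data.frame(female_id = "F01",
                   t = as.POSIXct("2011-05-02 00:00:00", tz = "UTC") + c(0, 4, 8, 12) * 3600,
                   lon = 31, lat = lat)
  dnd <- daily_net_displacement(tr)
  expect_equal(nrow(dnd), 1)
  expect_equal(dnd$dnd_km, 2, tolerance = 1e-9)
  expect_equal(dnd$n_steps, 3L)
  # stationary female: zero every day
  tr2 <- make_traj(rep(31, 12), rep(-24, 12))
  expect_true(all(daily_net_displacement(tr2)$dnd_km == 0))
})

test_that("detect_clusters: basic shapes and gap handling", {
  # all fixes within ~50 m: one cluster holding every fix
  set.seed(21)
  jit <- function(n, m) rnorm(n, 0, m / 111320)
  tr <- make_traj(31 + jit(10, 20), -24 + jit(10, 20))
  cl <- detect_clusters(tr)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_fixes, 10L)
  expect_lte(cl$max_radius_m, 200)
  # alternating fixes 1 km apart: no cluster at min_fixes = 3
  lon <- 31 + rep(c(0, 1 / 111.32 / cos(-24 * pi / 180)), 6)
  expect_equal(nrow(detect_clusters(make_traj(lon, rep(-24, 12)))), 0)
  # a schedule gap does not break a cluster
  tr3 <- make_traj(rep(31, 6), rep(-24, 6))
  tr3 <- tr3[-3, ] # dropped fix
  expect_equal(detect_clusters(tr3)$n_fixes, 5L)
})

test_that("clusters partition fixes and shrinking the radius never grows one", {
  tr <- random_trajectory(60, seed = 5)
  for (r in c(400, 200, 100)) {
    cl <- detect_clusters(tr, radius_m = r)
    if (nrow(cl) >= 2) {
      expect_true(all(diff(as.numeric(cl$start_t)) > 0))
      expect_true(all(cl$end_t[-nrow(cl)] < cl$start_t[-1]))
    }
    expect_true(all(cl$max_radius_m <= r))
  }
  big <- detect_clusters(tr, radius_m = 250)
  small <- detect_clusters(tr, radius_m = 120)
  expect_lte(if (nrow(small)) max(small$n_fixes) else 0L,
             if (nrow(big)) max(big$n_fixes) else 0L)
})

test_that("greedy clusters match the exhaustive oracle on random trajectories", {
  for (s in 1:30) {
    n <- sample(15:50, 1)
    tr <- random_trajectory(n, seed = 1000 + s)
    mf <- sample(2:4, 1)
    got <- detect_clusters(tr, radius_m = 200, min_fixes = mf)
    want <- oracle_clusters(tr$lon, tr$lat, 200, mf)
    expect_equal(nrow(got), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$n_fixes[i], length(want[[i]]))
      expect_equal(got$start_t[i], tr$t[want[[i]][1]])
      expect_equal(got$lon[i], mean(tr$lon[want[[i]]]), tolerance = 1e-12)
    }
  }
})

test_that("duration_of_stay summarizes and windows cluster durations", {
  tr <- make_traj(rep(31, 25), rep(-24, 25)) # one 4-day cluster
  cl <- detect_clusters(tr)
  s <- duration_of_stay(cl)
  expect_equal(s$n, 1)
  expect_equal(s$mean_days, 4)
  expect_equal(s$max_days, 4)
  # manual two-cluster table {4, 6} days
  cl2 <- data.frame(female_id = "F01",
                    start_t = t0 + c(0, 15) * 86400,
                    end_t = t0 + c(4, 21) * 86400,
                    n_fixes = c(25L, 37L),
                    duration_days = c(4, 6), lon = 31, lat = -24,
                    max_radius_m = 50)
  expect_equal(duration_of_stay(cl2)$mean_days, 5)
  expect_equal(duration_of_stay(cl2, "2011-05")$n, 2)
  none <- duration_of_stay(cl2, "2012-01")
  expect_equal(none$n, 0)
  expect_true(is.na(none$mean_days))
})
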