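test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_pregnant = 30), "exceeds")
  expect_error(sim_config(fix_failure_prob = c(south = 1.2, north = 0.1)),
               "probabilities")
  expect_error(sim_config(denning_step_km = c(south = 8, north = 5.81)),
               "below the ranging step")
  expect_error(sim_config(fix_interval_h = 5), "divide 24")
  expect_error(sim_config(n_months = 3), "too short")
  expect_error(sim_config(min_rest_separation_m = 300), "twice the residency radius")
})

test_that("environment calendar: seasons, rainfall split, determinism", {
  cfg <- sim_config(seed = 2)
  env <- simulate_environment(cfg)
  expect_equal(nrow(env), 2 * cfg$n_months)
  nov <- env$season[env$month == 11]
  jun <- env$season[env$month == 6]
  expect_true(all(nov == "wet"))
  expect_true(all(jun == "dry"))
  expect_true(all(env$prey_pulse[env$month %in% c(10, 1, 2, 3)]))
  expect_false(any(env$prey_pulse[env$month %in% c(5, 6, 7)]))
  # wet months carry ~80% of rainfall; south wetter than north
  for (reg in c("south", "north")) {
    e <- env[env$region == reg, ]
    frac <- sum(e$rainfall_mm[e$season == "wet"]) / sum(e$rainfall_mm)
    expect_gt(frac, 0.7)
  }
  expect_gt(mean(env$rainfall_mm[env$region == "south"]),
            mean(env$rainfall_mm[env$region == "north"]))
  expect_identical(env, simulate_environment(sim_config(seed = 2)))
  # zero rainfall scale: dry numbers, seasons still assigned
  env0 <- simulate_environment(sim_config(rainfall_annual_mm = c(south = 0, north = 0)))
  expect_true(all(env0$rainfall_mm == 0))
  expect_true(all(env0$season %in% c("wet", "dry")))
})

test_that("reproduction truth: gestation arithmetic and pregnancy flags", {
  cfg <- sim_config(seed = 5)
  tr <- draw_reproduction_truth(cfg)
  expect_equal(nrow(tr), 20)
  expect_equal(sum(tr$pregnant), 12)
  preg <- tr[tr$pregnant, ]
  expect_true(all(preg$conception_month ==
                    vapply(preg$birth_month, backdate_conception, "")))
  expect_true(all(month_index(preg$birth_month) >= month_index("2010-01")))
  expect_true(all(month_index(preg$birth_month) <= month_index("2012-12")))
  expect_true(all(is.na(tr$birth_month[!tr$pregnant])))
  # no pregnant females: no birth months anywhere
  tr0 <- draw_reproduction_truth(sim_config(n_pregnant = 0))
  expect_true(all(is.na(tr0$birth_month)))
})

test_that("fix grid: counts without failure, span, strict time order", {
  cfg <- sim_config(n_females_south = 1, n_females_north = 0, n_pregnant = 0,
                    start_month = "2010-04", n_months = 1,
                    fix_failure_prob = c(south = 0, north = 0), seed = 3)
  st <- simulate_study(cfg)
  traj <- st$trajectories[[1]]
  expect_equal(nrow(traj), 30 * 6) # 30 days x 6 fixes/day
  expect_true(all(diff(as.numeric(traj$t)) > 0))
  expect_true(all(civil_month_label(traj$t) == "2010-04"))
})

test_that("fix failure rate matches the configured probability", {
  st <- cached_study(1)
  for (reg in c("south", "north")) {
    ids <- st$truth$female_id[st$truth$region == reg]
    got <- sum(vapply(st$trajectories[ids], nrow, 0L))
    sched <- sum(vapply(st$trajectories[ids],
                        function(tr) attr(tr, "n_scheduled"), 0))
    p <- c(south = 0.15, north = 0.10)[[reg]]
    rate <- 1 - got / sched
    expect_gt(sched, 1e4)
    expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / sched))
  }
})

test_that("same seed gives identical studies, different seeds differ", {
  cfg <- function(s) sim_config(n_females_south = 2, n_females_north = 1,
                                n_pregnant = 1, n_months = 8, seed = s)
  a <- simulate_study(cfg(11))
  b <- simulate_study(cfg(11))
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$truth, b$truth)
  c3 <- simulate_study(cfg(12))
  expect_false(identical(a$trajectories[[1]]$lon, c3$trajectories[[1]]$lon))
})

test_that("per-female streams do not depend on who else is simulated", {
  big <- simulate_study(sim_config(n_females_south = 3, n_females_north = 0,
                                   n_pregnant = 0, n_months = 6, seed = 9))
  small <- simulate_study(sim_config(n_females_south = 1, n_females_north = 0,
                                     n_pregnant = 0, n_months = 6, seed = 9))
  expect_identical(big$trajectories[["S01"]], small$trajectories[["S01"]])
})

test_that("pregnant females den: long tight residency at the den site", {
  st <- cached_study(1)
  preg <- st$truth[st$truth$pregnant, ]
  for (i in seq_len(nrow(preg))) {
    traj <- st$trajectories[[preg$female_id[i]]]
    cl <- detect_clusters(traj)
    near <- haversine_km(cl$lon, cl$lat, preg$den_lon[i], preg$den_lat[i]) * 1000 < 300
    expect_true(any(near & cl$duration_days >= 10))
    # denning-month displacement below the female's overall ranging level
    dnd <- daily_net_displacement(traj)
    mo <- format(dnd$day, "%Y-%m")
    expect_lt(mean(dnd$dnd_km[mo == preg$birth_month[i]]),
              mean(dnd$dnd_km[mo != preg$birth_month[i]]))
  }
})
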