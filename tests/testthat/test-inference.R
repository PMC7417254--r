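test_that("conception backdating: examples, rollover, exact inverse", {
  expect_equal(backdate_conception("2011-06"), "2011-03")
  expect_equal(backdate_conception("2011-01"), "2010-10")
  expect_equal(backdate_conception("2011-07", gestation_months = 0), "2011-07")
  expect_equal(advance_conception("2010-10"), "2011-01")
  # exhaustive: every calendar month x gestation 1..3 round-trips exactly
  for (g in 1:3) {
    for (m in 1:12) {
      bm <- sprintf("2011-%02d", m)
      cm <- backdate_conception(bm, g)
      expect_identical(advance_conception(cm, g), bm)
      expect_equal(month_index(bm) - month_index(cm), g)
    }
  }
  # numeric month-index form is preserved too
  expect_identical(backdate_conception(24132L, 3), 24129L)
})

test_that("season classification", {
  expect_equal(season_of("2011-10"), "wet")
  expect_equal(season_of("2011-03"), "wet")
  expect_equal(season_of("2011-04"), "dry")
  expect_equal(season_of(c(10, 11, 12, 1, 2, 3)), rep("wet", 6))
  expect_equal(season_of(4:9), rep("dry", 6))
  expect_equal(season_of("2011-10", wet_months = 11:12), "dry")
})

test_that("default indicator weights normalize with the core dominating", {
  w <- default_indicator_weights()
  expect_equal(sum(w), 1)
  expect_setequal(names(w), c("core", "disp", "residency"))
  expect_gt(w[["core"]], w[["residency"]])
  expect_gt(w[["residency"]], w[["disp"]])
})

test_that("birth-month scoring: denning month wins, ties, baselines", {
  months <- sprintf("2011-%02d", 1:8)
  base <- data.frame(month = months,
                     dnd_km = c(7, 8, 7.5, 2.9, 7.2, 6.8, 7.9, 7.4),
                     core50_km2 = c(3.1, 3.6, 2.9, 0.2, 3.4, 3.2, 3.8, 3.0),
                     residency_days = c(4, 5, 4, 19, 6, 5, 4, 5))
  sc <- score_birth_months(base)
  expect_equal(sc$birth_month[1], "2011-04")
  expect_equal(sc$conception_month[1], "2011-01")
  expect_true(sc$called[1])
  expect_false(any(sc$called[-1]))
  expect_equal(sc$rank, seq_len(nrow(sc)))
  expect_equal(sc$max_residency_days[1], 19)
  expect_gt(sc$displacement_reduction_frac[1], 0.5)
  expect_lt(sc$core_contraction_ratio[1], 0.2)
  # flat metrics: all z-scores zero, nothing called
  flat <- data.frame(month = months, dnd_km = 7, core50_km2 = 3,
                     residency_days = 5)
  expect_false(any(score_birth_months(flat)$called))
  # perfect tie breaks to the earlier month
  tie <- data.frame(month = months[1:4], dnd_km = c(2, 7, 2, 7),
                    core50_km2 = c(1, 4, 1, 4), residency_days = c(9, 2, 9, 2))
  expect_equal(score_birth_months(tie)$birth_month[1], "2011-01")
  # insufficient baseline
  expect_error(score_birth_months(base[1:2, ]), "insufficient baseline")
  expect_error(score_birth_months(base[, -2]), "missing columns")
})

test_that("parturition fit: structure, methods, recovery on one study", {
  st <- cached_study(1)
  fit <- cached_fit(1)
  expect_s3_class(fit, "parturition")
  ids <- unique(fit$metrics$female_id)
  expect_setequal(ids, st$truth$female_id)
  expect_true(all(c("dnd_km", "core50_km2", "residency_days") %in% names(fit$metrics)))
  # every pregnant female is scored and her true birth month is a candidate
  preg <- st$truth[st$truth$pregnant, ]
  for (i in seq_len(nrow(preg))) {
    cc <- fit$candidates[fit$candidates$female_id == preg$female_id[i], ]
    expect_true(preg$birth_month[i] %in% cc$birth_month)
  }
  # top candidates of pregnant females mostly hit the truth on this study
  top <- fit$candidates[fit$candidates$rank == 1, ]
  hit <- vapply(seq_len(nrow(preg)), function(i) {
    tm <- top$birth_month[top$female_id == preg$female_id[i]]
    abs(month_index(tm) - month_index(preg$birth_month[i])) <= 1
  }, TRUE)
  expect_gte(mean(hit), 0.8)
  expect_output(print(fit), "Parturition detection fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.parturition")
  expect_output(print(s), "wet-season conception fraction")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("seasonal association: tallies, GLM table, degenerate inputs", {
  st <- cached_study(1)
  fit <- cached_fit(1)
  assoc <- seasonal_association(fit, st$env,
                                regions = setNames(st$truth$region,
                                                   st$truth$female_id))
  expect_s3_class(assoc, "seasonal_assoc")
  expect_setequal(assoc$tally$region, c("south", "north"))
  expect_true(all(assoc$tally$conception_fraction_wet >= 0 &
                    assoc$tally$conception_fraction_wet <= 1))
  for (resp in c("conception", "birth")) {
    tab <- assoc$models[[resp]]
    expect_s3_class(tab, "akaike_table")
    expect_equal(nrow(tab), 4)
    expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  }
  expect_output(print(assoc), "Conception models")
  # all-wet candidates give fraction 1
  cand <- data.frame(female_id = c("A", "B"), birth_month = c("2011-01", "2011-02"),
                     conception_month = c("2010-10", "2010-11"))
  env1 <- st$env[st$env$region == "south", ]
  a2 <- seasonal_association(cand, env1)
  expect_equal(a2$tally$conception_fraction_wet, 1)
  expect_error(seasonal_association(cand[0, ], env1), "no candidates")
})
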