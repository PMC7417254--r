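test_that("aic and aicc arithmetic", {
  expect_equal(aic(-6, 1), 14)
  expect_equal(aicc(14, 1, 20), 14 + 4 / 18)
  expect_equal(aicc(16.73, 2, 20), 16.73 + 12 / 17)
  expect_error(aicc(10, 4, 5), "n > k \\+ 1")
  # aicc >= aic, correction shrinks monotonically in n
  corr <- vapply(c(10, 20, 50, 200), function(n) aicc(30, 3, n) - 30, 0)
  expect_true(all(corr > 0))
  expect_true(all(diff(corr) < 0))
})

test_that("akaike_table basics: single model, symmetry, normalization", {
  expect_equal(akaike_table(42)$weight, 1)
  tw <- akaike_table(c(10, 10))
  expect_equal(tw$weight, c(0.5, 0.5))
  set.seed(6)
  for (r in 1:20) {
    v <- runif(sample(2:9, 1), 0, 500)
    tab <- akaike_table(v)
    expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
    # shifting every AICc by a constant changes nothing
    tab2 <- akaike_table(v + runif(1, -50, 50))
    expect_equal(tab2$weight, tab$weight, tolerance = 1e-12)
    expect_equal(tab2$delta, tab$delta, tolerance = 1e-10)
    # weights strictly decrease as delta increases
    o <- order(tab$delta)
    dd <- diff(tab$delta[o]) > 1e-12
    expect_true(all(diff(tab$weight[o])[dd] < 0))
  }
  # extreme deltas stay finite thanks to log-sum-exp
  tab <- akaike_table(c(0, 5000))
  expect_equal(tab$weight, c(1, 0))
  expect_error(akaike_table(c(1, NA)), "non-finite")
})

test_that("akaike_table accepts loglik/AIC forms and preserves row order", {
  tab <- akaike_table(data.frame(name = c("b", "a"), k = c(2, 1),
                                 loglik = c(-6.365, -6), n = 20))
  expect_equal(tab$name, c("b", "a"))
  expect_equal(tab$AIC, c(2 * 2 + 2 * 6.365, 14), tolerance = 1e-12)
  tab2 <- akaike_table(data.frame(name = c("b", "a"), k = c(2, 1),
                                  AIC = tab$AIC, n = 20))
  expect_equal(tab2$AICc, tab$AICc, tolerance = 1e-12)
})

test_that("denning model table reproduces the published arithmetic", {
  ref <- reference_aic_tables("denning")
  # AICc recomputed from the AIC column with n = 20 females matches print;
  # both printed columns are independently rounded, so allow two half-ulps
  re <- aicc(ref$AIC, ref$k, 20)
  expect_true(all(abs(re - ref$AICc) <= 0.011))
  expect_equal(round(re[1:3], 2), c(14.22, 17.44, 18.12), tolerance = 1e-12)
  tab <- akaike_table(ref$AICc, names = ref$model)
  expect_equal(tab$weight[1:3], c(0.74456, 0.14885, 0.10593), tolerance = 2e-3)
})

test_that("conception/birth model table reproduces the published arithmetic", {
  ref <- reference_aic_tables("conception_birth")
  re <- aicc(ref$AIC, ref$k, 20)
  expect_true(all(abs(re - ref$AICc) <= 0.011))
  tab <- akaike_table(re, names = paste(ref$response, ref$region))
  # deltas print as 2.91 / 4.64 / 2.23 / 0 in the table's row order
  expect_equal(round(tab$delta, 2), c(2.91, 4.64, 2.23, 0), tolerance = 1e-12)
  expect_equal(round(tab$weight, 2), c(0.14, 0.06, 0.20, 0.60), tolerance = 1e-12)
})

test_that("one-way ANOVA matches the textbook decomposition", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  # translation invariance
  g <- list(rnorm(5) + 1, rnorm(6), rnorm(4) - 2)
  a1 <- one_way_anova(g)
  a2 <- one_way_anova(lapply(g, `+`, 17.3))
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  # brute-force oracle on random instances
  set.seed(14)
  for (r in 1:15) {
    g <- lapply(sample(3:8, 3, replace = TRUE), rnorm)
    a <- one_way_anova(g)
    y <- unlist(g); lab <- rep(seq_along(g), lengths(g))
    ssb <- sum(lengths(g) * (vapply(g, mean, 0) - mean(y))^2)
    ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
    df1 <- length(g) - 1; df2 <- length(y) - length(g)
    Fo <- (ssb / df1) / (ssw / df2)
    expect_equal(a$F, Fo, tolerance = 1e-10)
    expect_equal(a$p, stats::pf(Fo, df1, df2, lower.tail = FALSE), tolerance = 1e-10)
  }
  # zero within-group variance, equal means: flagged undefined
  und <- one_way_anova(list(c(1, 1), c(1, 1)))
  expect_true(und$undefined)
})

test_that("Kruskal-Wallis matches a brute-force rank computation", {
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$H, 0)
  g <- list(c(1, 5, 9), c(2, 4), c(3, 8, 8))
  k1 <- kruskal_wallis(g)
  k2 <- kruskal_wallis(lapply(g, exp)) # monotone relabelling
  expect_equal(k1$H, k2$H, tolerance = 1e-12)
  set.seed(15)
  for (r in 1:15) {
    g <- lapply(sample(3:7, 3, replace = TRUE),
                function(n) sample(1:8, n, replace = TRUE))
    k <- kruskal_wallis(g)
    y <- unlist(g); lab <- rep(seq_along(g), lengths(g))
    rk <- rank(y); N <- length(y)
    Rbar <- tapply(rk, lab, mean)
    H <- 12 / (N * (N + 1)) * sum(lengths(g) * (Rbar - (N + 1) / 2)^2)
    ties <- table(y)
    H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
    expect_equal(k$H, H, tolerance = 1e-10)
    expect_equal(k$p, stats::pchisq(H, length(g) - 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("binary GLM: closed forms, oracle maximization, separation", {
  y <- rep(c(0, 1), each = 10)
  f <- fit_binary_glm(y, matrix(1, 20, 1))
  expect_equal(unname(f$coef), 0, tolerance = 1e-8)
  expect_equal(f$loglik, 20 * log(0.5), tolerance = 1e-10)
  expect_equal(f$aic, 2 - 2 * 20 * log(0.5), tolerance = 1e-10)
  expect_false(f$separation)
  # antisymmetric design: intercept stays at zero
  x <- c(-3, -2, -1, 1, 2, 3)
  ya <- c(0, 0, 1, 0, 1, 1)
  fa <- fit_binary_glm(ya, cbind(1, x))
  expect_equal(unname(fa$coef[1]), 0, tolerance = 1e-8)
  # independent likelihood maximization agrees
  set.seed(4)
  for (r in 1:8) {
    n <- 40
    X <- cbind(1, rnorm(n))
    yb <- rbinom(n, 1, plogis(0.3 * X[, 2] - 0.2))
    fit <- fit_binary_glm(yb, X)
    opt <- stats::optim(c(0, 0), function(b) -logistic_loglik(b, yb, X),
                        method = "BFGS")
    expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
    expect_gte(fit$loglik + 1e-9,
               fit_binary_glm(yb, X[, 1, drop = FALSE])$loglik)
  }
  # complete separation is flagged and still yields a finite fit
  xs <- c(-2, -1.5, -1, 1, 1.5, 2, 2.5, -2.5)
  ys <- as.numeric(xs > 0)
  fs <- fit_binary_glm(ys, cbind(1, xs))
  expect_true(fs$separation)
  expect_true(is.finite(fs$loglik))
  expect_error(fit_binary_glm(ys, cbind(1, xs, 2 * xs)), "rank deficient")
})
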