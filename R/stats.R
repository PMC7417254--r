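# Model-selection arithmetic (AIC, small-sample AICc, Akaike weights) and the
# group comparisons used downstream. The information-criterion arithmetic is
# authored here; ANOVA, Kruskal-Wallis and logistic fits are delegated to the
# stats package, which is what any practitioner would call.

#' Akaike information criterion
#'
#' @param loglik maximized log-likelihood of the model.
#' @param k number of estimated parameters.
#' @return `2k - 2*loglik`.
#' @examples
#' aic(-6, 1) # 14
#' @export
aic <- function(loglik, k) {
  stopifnot(is.finite(loglik), k >= 1)
  2 * k - 2 * loglik
}

#' Small-sample corrected AIC (AICc)
#'
#' Adds the correction `2k(k+1)/(n - k - 1)` to an AIC value; appropriate
#' when the effective sample size `n` is small relative to `k`.
#'
#' @param aic_value AIC of the model.
#' @param k number of estimated parameters.
#' @param n effective sample size; must exceed `k + 1`.
#' @return corrected AICc value.
#' @examples
#' aicc(14, 1, 20)    # 14.222...
#' aicc(16.73, 2, 20) # 17.436...
#' @export
aicc <- function(aic_value, k, n) {
  if (any(n <= k + 1)) stop("AICc undefined: need n > k + 1")
  aic_value + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike model-selection table
#'
#' Computes `delta_i = AICc_i - min(AICc)` and Akaike weights
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` for a candidate model set.
#' Weights are computed with log-sum-exp stabilization, so arbitrarily large
#' deltas are safe. Row order is preserved.
#'
#' @param x either a numeric vector of AICc values, or a data.frame with
#'   columns `name`, `k` and one of `AICc` or (`loglik`, `n`) or (`AIC`, `n`)
#'   from which AICc is derived.
#' @param names optional model labels when `x` is a numeric vector.
#' @return a `data.frame` of class `"akaike_table"` with columns
#'   `name, k, AIC, AICc, delta, weight` (criterion columns NA when not
#'   derivable from the input).
#' @examples
#' akaike_table(c(14.22, 17.44, 18.12))
#' @export
akaike_table <- function(x, names = NULL) {
  if (is.numeric(x)) {
    tab <- data.frame(
      name = names %||% paste0("model", seq_along(x)),
      k = NA_real_, AIC = NA_real_, AICc = as.numeric(x),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- as.data.frame(x)
    if (is.null(tab$name)) tab$name <- paste0("model", seq_len(nrow(tab)))
    if (is.null(tab$AIC) && !is.null(tab$loglik)) tab$AIC <- aic(tab$loglik, tab$k)
    if (is.null(tab$AICc)) {
      if (is.null(tab$AIC) || is.null(tab$n)) stop("need AICc, or AIC/loglik with k and n")
      tab$AICc <- aicc(tab$AIC, tab$k, tab$n)
    }
    tab <- tab[, intersect(c("name", "k", "AIC", "AICc"), names(tab)), drop = FALSE]
    if (is.null(tab$k)) tab$k <- NA_real_
    if (is.null(tab$AIC)) tab$AIC <- NA_real_
  }
  if (nrow(tab) < 1) stop("need at least one candidate model")
  if (any(!is.finite(tab$AICc))) stop("non-finite AICc value")
  delta <- tab$AICc - min(tab$AICc)
  lw <- -delta / 2
  w <- exp(lw - max(lw))
  tab$delta <- delta
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  class(tab) <- c("akaike_table", "data.frame")
  tab
}

#' @export
print.akaike_table <- function(x, digits = 4, ...) {
  cat("Model selection table (", nrow(x), " candidates)\n", sep = "")
  y <- as.data.frame(x)
  for (cc in c("AIC", "AICc", "delta", "weight"))
    y[[cc]] <- signif(y[[cc]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) across two
#' or more groups, as used to compare movement indicators between pregnant
#' and nonpregnant females and between regions.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `F`, `df1`, `df2`, `p`, and `undefined` flag (TRUE when
#'   within-group variance is zero so F is not defined).
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(y) - length(groups) < 1) stop("need at least 2 residual df")
  n <- length(y)
  gm <- mean(y)
  mns <- vapply(split(y, g), mean, 0)
  ssb <- sum(lengths(groups) * (mns - gm)^2)
  ssw <- sum((y - mns[as.integer(g)])^2)
  df1 <- length(groups) - 1L
  df2 <- n - length(groups)
  if (ssw <= .Machine$double.eps * sum(y^2)) {
    if (ssb <= .Machine$double.eps * max(1, sum(y^2)))
      return(list(F = 0, df1 = df1, df2 = df2, p = 1, undefined = TRUE))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0, undefined = TRUE))
  }
  # cross-check path: stats::oneway.test(var.equal = TRUE) gives the same F
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = unname(ft$p.value), undefined = FALSE)
}

#' Kruskal-Wallis rank-sum test
#'
#' Wrapper around [stats::kruskal.test()] (rank-based H with tie correction,
#' chi-square reference with `g - 1` df), used for fecundity comparisons
#' across reserves.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (length(unique(unlist(groups))) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = unname(kt$p.value))
}

#' Maximum-likelihood logistic regression fit
#'
#' Fits a binomial GLM with logit link to 0/1 outcomes by IRLS
#' ([stats::glm()]). Complete or quasi-complete separation is detected
#' (fitted probabilities collapsing to 0/1 with diverging coefficients); the
#' fit is then flagged and refit with a small ridge penalty so a finite,
#' deterministic log-likelihood is always reported.
#'
#' @param y numeric or logical 0/1 outcome vector.
#' @param X design matrix (including the intercept column if wanted).
#' @param ridge L2 penalty used only for the separation fallback.
#' @return list of class `"binary_glm"` with `coef`, `loglik` (unpenalized,
#'   at the returned coefficients), `k`, `n`, `aic`, `separation`.
#' @export
fit_binary_glm <- function(y, X, ridge = 1e-4) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (length(y) <= ncol(X)) stop("need n > number of coefficients")
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  p <- fit$fitted.values
  sep <- !fit$converged || any(p < 1e-8 | p > 1 - 1e-8) && max(abs(fit$coefficients)) > 15
  beta <- fit$coefficients
  if (sep) beta <- ridge_logistic(y, X, ridge)
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  k <- ncol(X)
  structure(list(coef = beta, loglik = ll, k = k, n = length(y),
                 aic = aic(ll, k), separation = sep),
            class = "binary_glm")
}

# Ridge-penalized logistic IRLS; the penalty keeps coefficients finite under
# separation while leaving well-posed problems essentially untouched.
ridge_logistic <- function(y, X, lambda, maxit = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    g <- crossprod(X, y - p) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' @export
print.binary_glm <- function(x, ...) {
  cat("Binomial GLM (logit link): n =", x$n, " k =", x$k,
      " logLik =", format(x$loglik, digits = 6),
      if (x$separation) " [separation: ridge-stabilized]" else "", "\n")
  print(x$coef)
  invisible(x)
}
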