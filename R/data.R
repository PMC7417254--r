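#' Reference candidate-model AIC tables
#'
#' The published AIC/AICc columns of the two candidate-model sets this
#' package's model-selection arithmetic is checked against: the denning-site
#' indicator models (seven candidates over 20 collared females; range,
#' biomass, step-length and disease covariates) and the per-region
#' conception/birth models (four candidates with prey-pulse and rainfall
#' predictors). Shipped as plain CSV under `extdata`.
#'
#' @param which `"denning"` or `"conception_birth"`.
#' @return data.frame with the printed `model`, `k`, `AIC` and `AICc`
#'   columns (plus `response`/`region` for the conception/birth set).
#' @export
reference_aic_tables <- function(which = c("denning", "conception_birth")) {
  which <- match.arg(which)
  f <- switch(which,
              denning = "denning_models_aic.csv",
              conception_birth = "conception_birth_models_aic.csv")
  read.csv(system.file("extdata", f, package = "lionden"),
           stringsAsFactors = FALSE, check.names = FALSE)
}
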