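#' Fallback estimation for data-sparse countries
#'
#' Countries whose observation base is too thin for the spline model --
#' fewer than four data points or less than ten years of coverage -- are
#' predicted from the cross-country relationship between youth and under-5
#' mortality: a mixed-effects regression of log(10q15) on log(under-5
#' mortality rate) with random intercepts and random slopes by region,
#' trained on the spline-model medians of the data-rich countries.
#'
#' @name sparse_predict
NULL

#' Is a country's observation base too sparse for the spline model?
#'
#' @param obs Observation rows of one country (band (15,10) rows are
#'   counted; excluded rows are not).
#' @return TRUE iff fewer than 4 usable observations or their reference
#'   times span less than 10 years.
#' @export
is_sparse <- function(obs) {
  obs <- obs[!obs$excluded & obs$age_start == 15 & obs$age_width == 10, ]
  nrow(obs) < 4 || diff(range(obs$ref_time)) < 10
}

#' Fit the mixed-effects log-log regression
#'
#' Restricted maximum likelihood via `lme4::lmer` of
#' `logq ~ logu5mr + (1 + logu5mr | region)`.  A singular or failed fit
#' falls back to fixed-effects OLS with a warning.
#'
#' @param pairs Data frame `logq` (log 10q15 estimate), `logu5mr`,
#'   `region`; at least 10 pairs from at least 2 regions.
#' @return Object of class `mixed_fit`: `fixed` (intercept, slope),
#'   `region_effects` (per-region intercept/slope deviations),
#'   `var_components` (intercept var, slope var, covariance, residual
#'   var), `n_obs`, `ols_fallback` flag.
#' @export
fit_mixed <- function(pairs) {
  if (nrow(pairs) < 10) stop("at least 10 training pairs are required")
  if (length(unique(pairs$region)) < 2) {
    warning("fewer than 2 regions; falling back to fixed-effects OLS")
    return(mixed_ols(pairs))
  }
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      logq ~ logu5mr + (1 + logu5mr | region), data = pairs, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixed-model fit failed; falling back to fixed-effects OLS")
    return(mixed_ols(pairs))
  }
  vc <- lme4::VarCorr(fit)$region
  re <- lme4::ranef(fit)$region
  fe <- lme4::fixef(fit)
  structure(
    list(fixed = c(intercept = unname(fe[1]), slope = unname(fe[2])),
         region_effects = data.frame(region = rownames(re),
                                     intercept = re[, 1], slope = re[, 2],
                                     stringsAsFactors = FALSE),
         var_components = c(var_intercept = vc[1, 1], var_slope = vc[2, 2],
                            covariance = vc[1, 2],
                            var_residual = attr(lme4::VarCorr(fit), "sc")^2),
         n_obs = nrow(pairs), ols_fallback = FALSE),
    class = "mixed_fit")
}

mixed_ols <- function(pairs) {
  fit <- stats::lm(logq ~ logu5mr, data = pairs)
  structure(
    list(fixed = c(intercept = unname(stats::coef(fit)[1]),
                   slope = unname(stats::coef(fit)[2])),
         region_effects = data.frame(region = character(), intercept = numeric(),
                                     slope = numeric(), stringsAsFactors = FALSE),
         var_components = c(var_intercept = 0, var_slope = 0, covariance = 0,
                            var_residual = summary(fit)$sigma^2),
         n_obs = nrow(pairs), ols_fallback = TRUE),
    class = "mixed_fit")
}

#' Predict 10q15 for a sparse country from its under-5 mortality series
#'
#' Point predictions combine the fixed effects with the region's estimated
#' deviations; for a region absent from the training data only the fixed
#' effects are used and the interval is widened by the full random-effect
#' variance.  Draws are emitted in the same `q_posterior` container as the
#' spline model, so downstream stages are source-agnostic.
#'
#' @param u5mr Data frame `year`, `u5mr` (under-5 mortality, per 1, > 0).
#' @param region Region identifier of the country.
#' @param fit A `mixed_fit`.
#' @param country Country identifier for the output container.
#' @param n_draws Number of normal draws on the log scale (default 1000).
#' @param seed Integer seed.
#' @return A `q_posterior` with `source = "sparse"`.
#' @export
predict_sparse <- function(u5mr, region, fit, country = "sparse",
                           n_draws = 1000, seed = 1) {
  stopifnot(inherits(fit, "mixed_fit"))
  if (any(u5mr$u5mr <= 0)) stop("u5mr must be strictly positive")
  x <- log(u5mr$u5mr)
  re <- fit$region_effects
  j <- match(region, re$region)
  vc <- fit$var_components
  if (!is.na(j)) {
    mu <- (fit$fixed["intercept"] + re$intercept[j]) +
      (fit$fixed["slope"] + re$slope[j]) * x
    v <- vc[["var_residual"]]
  } else {
    mu <- fit$fixed["intercept"] + fit$fixed["slope"] * x
    v <- vc[["var_residual"]] + vc[["var_intercept"]] +
      2 * x * vc[["covariance"]] + x^2 * vc[["var_slope"]]
  }
  v <- rep_len(v, length(x))
  draws <- with_seed(seed, {
    vapply(seq_along(x), function(i) stats::rnorm(n_draws, mu[i], sqrt(v[i])),
           numeric(n_draws))
  })
  q_posterior(country, u5mr$year, draws, source = "sparse")
}
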