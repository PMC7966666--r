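#' Out-of-sample validation of the fitted model
#'
#' The validation design refits the model on data *collected* before a
#' cutoff year (field date, not reference period: a 2015 survey is wholly
#' left out even where its recall windows refer to the 2000s) and compares
#' predictions with the left-out observations.  Errors are observed minus
#' predicted, in deaths per 1000, and coverage uses the predictive
#' interval for a new observation -- the latent-q interval widened by the
#' observation's sampling variance and the source-type non-sampling
#' variance -- not the latent interval itself.
#'
#' @name oos_validation
NULL

#' Split observations by collection date
#'
#' @param obs Observation table.
#' @param cutoff_year Collection-date cutoff (default 2013): training data
#'   were collected strictly before it.
#' @return List `training`, `leftout` (both observation tables).
#' @export
make_training_set <- function(obs, cutoff_year = 2013) {
  obs <- validate_observations(obs)
  train <- obs[obs$collection_time < cutoff_year, ]
  if (!nrow(train)) stop("training set is empty: no data collected before the cutoff")
  list(training = train, leftout = obs[obs$collection_time >= cutoff_year, ])
}

#' Evaluate refit predictions against left-out observations
#'
#' @param fit A `b3_fit` obtained from the training data only.
#' @param leftout Left-out observation rows (band (15,10) rows are
#'   evaluated).
#' @param bias_offset Constant added to predicted q (per 1) before
#'   comparison; used to verify the error sign convention (default 0).
#' @param seed Seed for the predictive-noise draws.
#' @return Object of class `validation_report`: `cutoff`-free list with
#'   `n_leftout`, `median_error` and `median_abs_error` (per 1000,
#'   observed minus predicted), `coverage90`, and per-observation
#'   `records`.
#' @export
evaluate_predictions <- function(fit, leftout, bias_offset = 0, seed = 1) {
  leftout <- leftout[!leftout$excluded & leftout$age_start == 15 &
                       leftout$age_width == 10, ]
  if (!nrow(leftout)) stop("no left-out band-(15,10) observations to evaluate")
  omega_med <- if (length(fit$omega_draws)) {
    apply(fit$omega_draws, 2, stats::median)
  } else numeric(0)
  records <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(leftout))) {
      o <- leftout[i, ]
      post <- fit$posteriors[[o$country]]
      if (is.null(post)) next
      t_years <- post$years + 0.5
      if (o$ref_time < min(t_years) || o$ref_time > max(t_years) + 0.5) next
      logq_draws <- apply(post$draws, 1, function(row) {
        interp_series(t_years, row, o$ref_time)
      })
      q_pred <- exp(logq_draws) + bias_offset
      med <- stats::median(q_pred)
      om <- if (o$source_type %in% names(omega_med)) omega_med[[o$source_type]] else 0
      pred_new <- q_pred * exp(stats::rnorm(length(q_pred), 0,
                                            sqrt(o$se_logq^2 + om^2)))
      ci <- stats::quantile(pred_new, c(0.05, 0.95), names = FALSE)
      records[[length(records) + 1]] <- data.frame(
        country = o$country, series_id = o$series_id,
        source_type = o$source_type, ref_time = o$ref_time,
        q_obs = o$q, q_pred = med,
        error_per1000 = 1000 * (o$q - med),
        covered = o$q >= ci[1] & o$q <= ci[2],
        stringsAsFactors = FALSE)
    }
  })
  rec <- do.call(rbind, records)
  if (is.null(rec) || !nrow(rec)) stop("no left-out observations matched fitted countries")
  structure(
    list(n_leftout = nrow(rec),
         median_error = stats::median(rec$error_per1000),
         median_abs_error = stats::median(abs(rec$error_per1000)),
         coverage90 = mean(rec$covered),
         records = rec),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("out-of-sample validation: n = %d, median error %.2f,",
                     " median |error| %.2f (per 1000), 90%% coverage %.3f\n"),
              x$n_leftout, x$median_error, x$median_abs_error, x$coverage90))
  invisible(x)
}
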