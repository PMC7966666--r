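#' Log-quadratic plausibility screen for survey and census series
#'
#' Sibling histories and census household-death reports can understate
#' youth mortality badly enough that no bias model should be asked to
#' rescue them.  The screen fits the expected relation between log 10q15
#' and log 5q0 on a reference set of paired measurements (in this package a
#' synthetic reference carrying the in-world link; a fit from real
#' reference data can be substituted) and excludes whole survey series
#' whose pooled 10q15 falls below the lower bound of the 95% prediction
#' interval at their pooled 5q0.  The rule is one-sided: implausibly *low*
#' youth mortality relative to child mortality signals death underreporting.
#'
#' @name quality_screen
NULL

#' Fit the log-quadratic reference regression
#'
#' Ordinary least squares of `log(q10_15)` on `1, x, x^2` with
#' `x = log(q5_0)`; the residual variance uses the `n - 3` denominator and
#' the design cross-product inverse is stored for prediction variances.
#'
#' @param reference_pairs Data frame with columns `q5_0` and `q10_15`,
#'   both per 1 in (0, 1); more than 10 pairs required.
#' @return Object of class `logquad_fit`: `beta` (length 3), `sigma2`,
#'   `n_ref`, `xtx_inverse`, `x_mean`.
#' @export
fit_logquad <- function(reference_pairs) {
  q5 <- reference_pairs$q5_0
  q15 <- reference_pairs$q10_15
  if (any(q5 <= 0 | q5 >= 1) || any(q15 <= 0 | q15 >= 1)) {
    stop("reference probabilities must lie in (0, 1)")
  }
  n <- length(q5)
  if (n <= 10) stop("the reference fit needs more than 10 pairs")
  x <- log(q5)
  X <- cbind(1, x, x^2)
  y <- log(q15)
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-12) stop("degenerate (collinear) reference design")
  xtx_inv <- solve(xtx)
  beta <- drop(xtx_inv %*% crossprod(X, y))
  resid <- y - drop(X %*% beta)
  structure(
    list(beta = beta, sigma2 = sum(resid^2) / (n - 3), n_ref = n,
         xtx_inverse = xtx_inv, x_mean = mean(x)),
    class = "logquad_fit"
  )
}

#' Prediction bounds of the log-quadratic reference at a given 5q0
#'
#' Two-sided 95% prediction interval for a new log 10q15 at `q5_0`:
#' mean plus/minus `t(n-3, 0.975) * sqrt(sigma2 * (1 + leverage))`,
#' exponentiated back to the q scale.
#'
#' @param fit A `logquad_fit`.
#' @param q5_0 Under-5 mortality, per 1, in (0, 1); vectorised.
#' @param level Interval level (default 0.95).
#' @param meas_var Measurement variance (log scale) of the value to be
#'   compared against the interval; widens the bounds so the interval is
#'   predictive for the *observed* quantity, not the latent one (default 0).
#' @return Data frame `q5_0`, `expected`, `lower`, `upper` on the q scale.
#' @export
prediction_bounds <- function(fit, q5_0, level = 0.95, meas_var = 0) {
  stopifnot(inherits(fit, "logquad_fit"))
  if (any(q5_0 <= 0 | q5_0 >= 1)) stop("q5_0 must lie in (0, 1)")
  x <- log(q5_0)
  X0 <- cbind(1, x, x^2)
  mu <- drop(X0 %*% fit$beta)
  lev <- rowSums((X0 %*% fit$xtx_inverse) * X0)
  half <- stats::qt(1 - (1 - level) / 2, fit$n_ref - 3) *
    sqrt(fit$sigma2 * (1 + lev) + meas_var)
  data.frame(q5_0 = q5_0, expected = exp(mu),
             lower = exp(mu - half), upper = exp(mu + half))
}

#' Screen survey and census series against the reference relation
#'
#' Pools each series' 10q15 and 5q0 observations by inverse-variance
#' weighting on the log scale, computes the lower 95% prediction bound at
#' the pooled 5q0, and flags the whole series excluded (reason
#' `below_logquad_lower`) when the pooled 10q15 falls below it.  VR and SRS
#' series are never screened; series without a paired 5q0 pass with a
#' warning.
#'
#' @param obs Observation table; paired 5q0 measurements are rows of the
#'   same `series_id` with age band (0, 5).
#' @param fit A `logquad_fit`.
#' @param level Prediction-interval level (default 0.95).
#' @param nonsampling_sd Allowance for non-sampling measurement error of a
#'   survey series on the log scale (default 0.05), included in the
#'   predictive variance alongside the pooled sampling error: the reported
#'   SEs of retrospective series understate their total error.
#' @return List with `observations` (flags updated) and `report` (one row
#'   per screened series: pooled values, bound, decision).
#' @export
screen_surveys <- function(obs, fit, level = 0.95, nonsampling_sd = 0.05) {
  obs <- validate_observations(obs)
  screened_types <- c("sibling", "census")
  sids <- unique(obs$series_id[obs$source_type %in% screened_types])
  report <- list()
  for (sid in sids) {
    rows <- obs$series_id == sid
    y15 <- rows & obs$age_start == 15
    y05 <- rows & obs$age_start == 0
    if (!any(y05)) {
      warning(sprintf("series %s has no paired under-5 observation; passed unscreened", sid))
      next
    }
    pooled_q15 <- exp(pool_log(obs$q[y15], obs$se_logq[y15]))
    pooled_q5 <- exp(pool_log(obs$q[y05], obs$se_logq[y05]))
    # sampling error of the pooled estimates, propagated through the curve
    slope_at <- fit$beta[2] + 2 * fit$beta[3] * log(pooled_q5)
    mvar <- 1 / sum(1 / obs$se_logq[y15]^2) +
      slope_at^2 / sum(1 / obs$se_logq[y05]^2) + nonsampling_sd^2
    lb <- prediction_bounds(fit, pooled_q5, level, meas_var = mvar)$lower
    drop_it <- pooled_q15 < lb
    if (drop_it) {
      obs$excluded[rows] <- TRUE
      obs$exclusion_reason[rows] <- "below_logquad_lower"
    }
    report[[length(report) + 1]] <- data.frame(
      series_id = sid, pooled_q15_24 = pooled_q15, pooled_q5_0 = pooled_q5,
      lower_bound = lb, decision = if (drop_it) "excluded" else "kept",
      stringsAsFactors = FALSE)
  }
  list(observations = obs,
       report = do.call(rbind, report) %||%
         data.frame(series_id = character(), pooled_q15_24 = numeric(),
                    pooled_q5_0 = numeric(), lower_bound = numeric(),
                    decision = character()))
}

# inverse-variance weighted mean of log q
pool_log <- function(q, se) {
  w <- 1 / se^2
  sum(w * log(q)) / sum(w)
}

#' Build a synthetic reference set of (5q0, 10q15) pairs
#'
#' Samples country-years from generated trajectories to stand in for the
#' historical reference databases; the pairs carry the generator's
#' log-quadratic link plus country noise.
#'
#' @param truth Trajectories from [generate_truth()] (crisis years are
#'   dropped: the reference relation describes normal mortality regimes).
#' @param per_country Number of years sampled per country (default 8).
#' @param seed Integer seed.
#' @return Data frame `q5_0`, `q10_15`.
#' @export
reference_pairs <- function(truth, per_country = 8, seed = 1) {
  truth <- truth[!truth$crisis, ]
  with_seed(seed, {
    rows <- unlist(lapply(split(seq_len(nrow(truth)), truth$country), function(ix) {
      sample(ix, min(per_country, length(ix)))
    }))
    data.frame(q5_0 = truth$q5_0_true[rows], q10_15 = truth$q15_24_true[rows])
  })
}
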