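#' Splitting 10q15 into 5q15 and 5q20
#'
#' Death counts require band-specific probabilities.  The split is driven
#' by r, the ratio of 5q15 to the median model estimate of 10q15, modelled
#' on the logit scale with a penalized B-spline so the estimated share
#' moves smoothly over time.  The ratio curve is applied to every posterior
#' draw, so the split inherits all of its uncertainty from the 10q15
#' posterior, and the composition identity
#' `compose_q(5q15, 5q20) == 10q15` holds draw by draw.
#'
#' @name age_split
NULL

#' Build logit-ratio observations from 5q15 measurements
#'
#' @param obs_5q15 Observation rows with age band (15, 5): columns
#'   `ref_time`, `q`, `se_logq`.
#' @param posterior A `q_posterior` of log 10q15 for the same country.
#' @return Data frame `t`, `logit_r`, `weight`, `clipped`; r is clipped to
#'   (0.01, 0.99) with the flag set.
#' @export
ratio_observations <- function(obs_5q15, posterior) {
  med <- apply(exp(posterior$draws), 2, stats::median)
  if (any(med <= 0)) stop("posterior median 10q15 is zero; cannot form ratios")
  m_at <- interp_series(posterior$years + 0.5, med, obs_5q15$ref_time)
  r <- obs_5q15$q / m_at
  clipped <- r <= 0.01 | r >= 0.99
  r <- pmin(pmax(r, 0.01), 0.99)
  data.frame(t = obs_5q15$ref_time, logit_r = stats::qlogis(r),
             weight = 1 / obs_5q15$se_logq^2, clipped = clipped)
}

#' Fit a penalized spline to logit-ratio observations
#'
#' Weighted penalized least squares on the package's B-spline basis with a
#' second-difference penalty; the penalty is chosen by generalized
#' cross-validation over a bounded log-spaced grid.  With two or fewer
#' observations the fit falls back to a constant (their weighted mean).
#'
#' @param ratio_obs Data frame from [ratio_observations()] (or any frame
#'   with `t`, `logit_r`, `weight`).
#' @param years Integer years on which to return the fitted ratio.
#' @param penalty Optional fixed penalty; `NULL` (default) selects by GCV.
#' @param basis Optional `spline_basis` covering `years` and the
#'   observation times.
#' @return Object of class `ratio_fit`: `country`-agnostic list with
#'   `years`, `r_hat` in (0, 1), `smoothing_penalty`, `n_obs_used`.
#' @export
fit_ratio_spline <- function(ratio_obs, years, penalty = NULL, basis = NULL) {
  n <- nrow(ratio_obs)
  if (n <= 2) {
    val <- if (n == 0) 0 else
      sum(ratio_obs$weight * ratio_obs$logit_r) / sum(ratio_obs$weight)
    return(structure(list(years = as.integer(years),
                          r_hat = rep(stats::plogis(val), length(years)),
                          smoothing_penalty = Inf, n_obs_used = n),
                     class = "ratio_fit"))
  }
  if (is.null(basis)) {
    rng <- range(c(years, floor(ratio_obs$t), ceiling(ratio_obs$t)))
    basis <- build_basis(rng[1], rng[2] + 1, knot_spacing = 2.5)
  }
  B <- eval_basis(basis, ratio_obs$t)
  Bg <- eval_basis(basis, years + 0.5)
  D <- diff2_matrix(basis$n_basis)
  DtD <- crossprod(D)
  w <- ratio_obs$weight / mean(ratio_obs$weight)
  y <- ratio_obs$logit_r
  BtWB <- crossprod(B, w * B)
  BtWy <- crossprod(B, w * y)
  # ridge towards a line: tiny extra penalty keeps the system full rank
  P0 <- diag(1e-8, basis$n_basis)
  solve_pen <- function(lam) {
    theta <- solve(BtWB + lam * DtD + P0, BtWy)
    fitted <- drop(B %*% theta)
    edf <- sum(diag(solve(BtWB + lam * DtD + P0, BtWB)))
    list(theta = theta, fitted = fitted, edf = edf)
  }
  if (is.null(penalty)) {
    grid <- 10^seq(-2, 6, length.out = 25)
    gcv <- vapply(grid, function(lam) {
      f <- solve_pen(lam)
      rss <- sum(w * (y - f$fitted)^2)
      n * rss / (n - min(f$edf, n - 0.5))^2
    }, numeric(1))
    penalty <- grid[which.min(gcv)]
  }
  f <- solve_pen(penalty)
  structure(list(years = as.integer(years),
                 r_hat = stats::plogis(drop(Bg %*% f$theta)),
                 smoothing_penalty = penalty, n_obs_used = n),
            class = "ratio_fit")
}

#' Apply the ratio curve to split posterior draws by age band
#'
#' Per draw and year: `5q15 = r_hat * 10q15` and
#' `5q20 = 1 - (1 - 10q15)/(1 - 5q15)`, so composing the two bands
#' reproduces the draw's 10q15 exactly.
#'
#' @param posterior A `q_posterior` of log 10q15.
#' @param fit A `ratio_fit` aligned on the same years (subsets allowed).
#' @return List with matrices `q15_19` and `q20_24` (draws by years, q
#'   scale) and the `years` used.
#' @export
apply_split <- function(posterior, fit) {
  years <- intersect(posterior$years, fit$years)
  if (!length(years)) stop("posterior and ratio fit share no years")
  q <- exp(posterior$draws[, match(years, posterior$years), drop = FALSE])
  r <- fit$r_hat[match(years, fit$years)]
  q1 <- sweep(q, 2, r, `*`)
  q2 <- 1 - (1 - q) / (1 - q1)
  list(years = years, q15_19 = q1, q20_24 = q2)
}
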