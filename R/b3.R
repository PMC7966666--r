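#' Bayesian B-spline bias-reduction model for 10q15 trends
#'
#' The estimator at the core of the package.  For observation i in country
#' c, series s, at time t with retrospective lag `lag`:
#' \deqn{\log q_i = \sum_k \alpha_{c,k} B_k(t_i) + \delta_i (b_{0,s} + b_{1,s} lag_i) + \epsilon_i,
#'       \quad \epsilon_i \sim N(0, se_i^2 + \omega^2_{type(i)})}
#' so each observed probability is the latent risk times a source-specific
#' error multiplier (additive on the log scale).  \eqn{\delta_i = 1} for
#' sibling and census sources and 0 for VR/SRS; survey biases (level b0,
#' recall slope b1) are exchangeable across series through a hierarchical
#' normal model.  Second-order differences of the spline coefficients are
#' shrunk towards zero with a country-specific smoothing SD \eqn{\lambda_c}
#' whose log is itself exchangeable across countries, so countries share
#' information on how far log 10q15 may deviate from a linear trend.
#' Sampling is by a seeded adaptive Metropolis-within-Gibbs scheme with
#' conjugate normal updates for the spline coefficients, the survey biases
#' and the hierarchical means.
#'
#' @name b3_model
NULL

#' Configuration for the B3 model fit
#'
#' @param knot_spacing Knot spacing of the cubic B-spline basis, in years
#'   (default 2.5, about one coefficient per 2.5 years).
#' @param degree Spline degree (default 3).
#' @param penalty_order Difference penalty order (only 2 is supported: the
#'   penalty shrinks towards a linear trend in log q).
#' @param chains Number of MCMC chains (default 4).
#' @param warmup Adaptation iterations per chain, discarded (default 500).
#' @param samples Retained iterations per chain (default 1000).
#' @param seed Integer seed; chains use derived sub-seeds.
#' @param projection_year Last year of the estimates grid (default 2019).
#' @param adapt_target Metropolis acceptance target (default 0.44).
#' @param hyper Named list of hyperprior settings: `mu_b_sd` (SD 0.5 of the
#'   normal priors on the bias-mean parameters mu0, mu1), `tau_sd`
#'   (half-normal SD 0.5 on tau0, tau1, sigma_lambda and the omegas),
#'   `mu_lambda_mean`/`mu_lambda_sd` (normal prior on the mean log
#'   smoothing SD, default -3 and 1), `level_slope_sd` (SD 2 of the weak
#'   prior on the level and slope components of alpha, centred on a
#'   per-country data-driven line).
#' @return List of class `b3_config`.
#' @export
b3_config <- function(knot_spacing = 2.5, degree = 3, penalty_order = 2,
                      chains = 4, warmup = 500, samples = 1000, seed = 1,
                      projection_year = 2019, adapt_target = 0.44,
                      hyper = list()) {
  if (penalty_order != 2) stop("only a second-order difference penalty is supported")
  h <- list(mu_b_sd = 0.5, tau_sd = 0.5, mu_lambda_mean = -3,
            mu_lambda_sd = 1, level_slope_sd = 2)
  h[names(hyper)] <- hyper
  structure(list(knot_spacing = knot_spacing, degree = degree,
                 penalty_order = penalty_order, chains = chains,
                 warmup = warmup, samples = samples, seed = seed,
                 projection_year = projection_year,
                 adapt_target = adapt_target, hyper = h),
            class = "b3_config")
}

#' Fit the B3 model to an observation table
#'
#' Countries are fitted jointly: conditional on the shared hyperparameters
#' (bias means and SDs, smoothing hyperprior, source variances) the
#' country-level updates are independent.  Each country needs at least 4
#' included band-(15,10) observations spanning at least 10 years; countries
#' below that threshold belong to the sparse-country fallback
#' ([predict_sparse()]).
#'
#' @param obs Observation table ([validate_observations()]); excluded rows
#'   and under-5 pairing rows are ignored.  If crisis adjustment is to be
#'   applied afterwards, crisis-year observations must have been excluded
#'   before fitting.
#' @param basis Optional `spline_basis`; by default built from the data
#'   span and `config$projection_year` at `config$knot_spacing`.
#' @param config A [b3_config()].
#' @return Object of class `b3_fit`: `posteriors` (named list of
#'   `q_posterior` objects, one per country, holding `draws` =
#'   draws-by-years matrix of log q), `alpha_draws`, `bias_draws` (matrix
#'   with columns b0/b1 per series), `lambda_draws`, `omega_draws`,
#'   `hyper_draws`, `chain_id`, `convergence` (split R-hat and effective
#'   sample size of log q at 1990/2000/projection year), `basis`, `config`.
#' @export
fit_b3 <- function(obs, basis = NULL, config = b3_config()) {
  obs <- validate_observations(obs)
  obs <- obs[!obs$excluded & obs$age_start == 15 & obs$age_width == 10, ]
  if (!nrow(obs)) stop("no usable band-(15,10) observations")
  countries <- sort(unique(obs$country))
  for (cc in countries) {
    oc <- obs[obs$country == cc, ]
    if (nrow(oc) < 4 || diff(range(oc$ref_time)) < 10) {
      stop(sprintf(paste0("country %s has fewer than 4 observations or less than",
                          " 10 years of coverage; use the sparse-country model"), cc))
    }
  }
  year_min <- floor(min(obs$ref_time))
  year_max <- max(config$projection_year + 1, ceiling(max(obs$ref_time)))
  if (is.null(basis)) {
    basis <- build_basis(year_min, year_max, config$knot_spacing, config$degree)
  }
  dat <- b3_prepare(obs, basis, config)
  years_grid <- seq(floor(basis$domain[1]), config$projection_year)
  B_grid <- eval_basis(basis, years_grid + 0.5)
  n_iter <- config$warmup + config$samples
  chains <- lapply(seq_len(config$chains), function(ch) {
    b3_run_chain(dat, config, child_seed(config$seed, ch), n_iter, B_grid)
  })
  b3_collect(chains, dat, basis, config, years_grid)
}

# ---- internal: data preparation -------------------------------------------

b3_prepare <- function(obs, basis, config) {
  countries <- sort(unique(obs$country))
  lag <- obs_lag(obs)
  bias_on <- obs$source_type %in% c("sibling", "census")
  series_ids <- sort(unique(obs$series_id[bias_on]))
  K <- basis$n_basis
  D <- diff2_matrix(K)
  DtD <- crossprod(D)
  U <- qr.Q(qr(cbind(1, basis$greville - mean(basis$greville))))
  P0 <- tcrossprod(U) / config$hyper$level_slope_sd^2
  cdat <- lapply(countries, function(cc) {
    ix <- which(obs$country == cc)
    oc <- obs[ix, ]
    B <- eval_basis(basis, oc$ref_time)
    # data-driven straight line in coefficient space (prior centre)
    w <- 1 / oc$se_logq^2
    X <- cbind(1, oc$ref_time - mean(basis$greville))
    ab <- tryCatch(solve(crossprod(X, w * X), crossprod(X, w * log(oc$q))),
                   error = function(e) c(mean(log(oc$q)), 0))
    alpha0 <- drop(ab[1] + ab[2] * (basis$greville - mean(basis$greville)))
    list(country = cc, y = log(oc$q), se2 = oc$se_logq^2, B = B,
         type = oc$source_type, lag = lag[ix], series = oc$series_id,
         bias_on = bias_on[ix], alpha0 = alpha0,
         last_obs = max(oc$ref_time))
  })
  names(cdat) <- countries
  sdat <- lapply(series_ids, function(s) {
    cc <- obs$country[obs$series_id == s][1]
    list(series = s, country = cc)
  })
  names(sdat) <- series_ids
  omega_types <- setdiff(sort(unique(obs$source_type)), "vr_complete")
  list(countries = countries, cdat = cdat, series = series_ids, sdat = sdat,
       omega_types = omega_types, K = K, D = D, DtD = DtD, P0 = P0)
}

# ---- internal: one chain ---------------------------------------------------

b3_run_chain <- function(dat, config, seed, n_iter, B_grid) {
  with_seed(seed, {
    K <- dat$K
    nC <- length(dat$countries)
    nS <- length(dat$series)
    nT <- length(dat$omega_types)
    h <- config$hyper
    # state
    alpha <- lapply(dat$cdat, function(cd) cd$alpha0)
    eta <- lapply(dat$cdat, function(cd) drop(cd$B %*% cd$alpha0))
    lam <- rep(0.05, nC)
    b0 <- rep(0, nS); b1 <- rep(0, nS)
    bias <- lapply(dat$cdat, function(cd) rep(0, length(cd$y)))
    mu0 <- 0; mu1 <- 0
    tau0 <- 0.1; tau1 <- 0.02
    mu_lam <- h$mu_lambda_mean; sig_lam <- 0.5
    omega <- stats::setNames(rep(0.05, nT), dat$omega_types)
    # adaptive Metropolis scales
    sc <- list(lam = rep(0.5, nC), omega = stats::setNames(rep(0.5, nT), dat$omega_types),
               tau0 = 0.5, tau1 = 0.5, sig_lam = 0.5)
    n_keep <- config$samples
    G <- ncol(B_grid) ; nyg <- nrow(B_grid)
    logq_draws <- lapply(seq_len(nC), function(i) matrix(NA_real_, n_keep, nyg))
    alpha_draws <- lapply(seq_len(nC), function(i) matrix(NA_real_, n_keep, K))
    bias_draws <- matrix(NA_real_, n_keep, 2 * nS)
    lambda_draws <- matrix(NA_real_, n_keep, nC)
    omega_draws <- matrix(NA_real_, n_keep, nT)
    hyper_draws <- matrix(NA_real_, n_keep, 6)
    half_norm <- function(x, s) stats::dnorm(x, 0, s, log = TRUE) + log(2)
    obs_w <- function(cd) 1 / (cd$se2 + ifelse(cd$type == "vr_complete", 0,
                                               omega[cd$type]^2))
    for (it in seq_len(n_iter)) {
      adapting <- it <= config$warmup
      gam <- min(0.05, 1 / sqrt(it))
      # -- spline coefficients per country (conjugate normal)
      for (ci in seq_len(nC)) {
        cd <- dat$cdat[[ci]]
        w <- obs_w(cd)
        z <- cd$y - bias[[ci]]
        Q <- crossprod(cd$B, w * cd$B) + dat$DtD / lam[ci]^2 + dat$P0
        rhs <- crossprod(cd$B, w * z) + dat$P0 %*% cd$alpha0
        R <- chol(Q)
        mean_a <- backsolve(R, forwardsolve(t(R), rhs))
        a <- drop(mean_a + backsolve(R, stats::rnorm(K)))
        alpha[[ci]] <- a
        eta[[ci]] <- drop(cd$B %*% a)
      }
      # -- survey/census bias terms (conjugate bivariate normal)
      if (nS) {
        for (si in seq_len(nS)) {
          sd_ <- dat$sdat[[si]]
          ci <- match(sd_$country, dat$countries)
          cd <- dat$cdat[[ci]]
          rows <- which(cd$series == sd_$series)
          w <- obs_w(cd)[rows]
          r <- cd$y[rows] - eta[[ci]][rows]
          X <- cbind(1, cd$lag[rows])
          V <- crossprod(X, w * X) + diag(c(1 / tau0^2, 1 / tau1^2))
          rhs <- crossprod(X, w * r) + c(mu0 / tau0^2, mu1 / tau1^2)
          R <- chol(V)
          mb <- backsolve(R, forwardsolve(t(R), rhs))
          bb <- drop(mb + backsolve(R, stats::rnorm(2)))
          b0[si] <- bb[1]; b1[si] <- bb[2]
          bias[[ci]][cd$series == sd_$series] <-
            bb[1] + bb[2] * cd$lag[cd$series == sd_$series]
        }
      }
      # -- smoothing SDs (Metropolis on log lambda)
      for (ci in seq_len(nC)) {
        d <- dat$D %*% alpha[[ci]]
        ll <- function(l) sum(stats::dnorm(d, 0, l, log = TRUE)) +
          stats::dnorm(log(l), mu_lam, sig_lam, log = TRUE)
        prop <- lam[ci] * exp(stats::rnorm(1, 0, sc$lam[ci]))
        acc <- min(1, exp(ll(prop) - ll(lam[ci])))
        if (stats::runif(1) < acc) lam[ci] <- prop
        if (adapting) sc$lam[ci] <- exp(log(sc$lam[ci]) + gam * (acc - config$adapt_target))
      }
      # -- source-type non-sampling SDs (Metropolis on log omega)
      for (tt in dat$omega_types) {
        e2 <- numeric(0); se2 <- numeric(0)
        for (ci in seq_len(nC)) {
          cd <- dat$cdat[[ci]]
          sel <- cd$type == tt
          if (any(sel)) {
            e2 <- c(e2, (cd$y[sel] - eta[[ci]][sel] - bias[[ci]][sel])^2)
            se2 <- c(se2, cd$se2[sel])
          }
        }
        if (!length(e2)) next
        ll <- function(o) -0.5 * sum(log(se2 + o^2) + e2 / (se2 + o^2)) +
          half_norm(o, h$tau_sd)
        prop <- omega[tt] * exp(stats::rnorm(1, 0, sc$omega[tt]))
        acc <- min(1, exp(ll(prop) - ll(omega[tt]) + log(prop) - log(omega[tt])))
        if (stats::runif(1) < acc) omega[tt] <- prop
        if (adapting) sc$omega[tt] <- exp(log(sc$omega[tt]) + gam * (acc - config$adapt_target))
      }
      # -- hierarchical bias means (conjugate) and SDs (Metropolis)
      if (nS) {
        mu0 <- post_normal_mean(b0, tau0, 0, h$mu_b_sd)
        mu1 <- post_normal_mean(b1, tau1, 0, h$mu_b_sd)
        up <- mh_scale_sd(b0, mu0, tau0, sc$tau0, h$tau_sd, adapting, gam, config$adapt_target)
        tau0 <- up$value; sc$tau0 <- up$scale
        up <- mh_scale_sd(b1, mu1, tau1, sc$tau1, h$tau_sd, adapting, gam, config$adapt_target)
        tau1 <- up$value; sc$tau1 <- up$scale
      }
      mu_lam <- post_normal_mean(log(lam), sig_lam, h$mu_lambda_mean, h$mu_lambda_sd)
      up <- mh_scale_sd(log(lam), mu_lam, sig_lam, sc$sig_lam, h$tau_sd,
                        adapting, gam, config$adapt_target)
      sig_lam <- up$value; sc$sig_lam <- up$scale
      # -- store
      if (!adapting) {
        k <- it - config$warmup
        for (ci in seq_len(nC)) {
          logq_draws[[ci]][k, ] <- drop(B_grid %*% alpha[[ci]])
          alpha_draws[[ci]][k, ] <- alpha[[ci]]
        }
        if (nS) bias_draws[k, ] <- c(rbind(b0, b1))
        lambda_draws[k, ] <- lam
        if (nT) omega_draws[k, ] <- omega
        hyper_draws[k, ] <- c(mu0, tau0, mu1, tau1, mu_lam, sig_lam)
      }
    }
    list(logq = logq_draws, alpha = alpha_draws, bias = bias_draws,
         lambda = lambda_draws, omega = omega_draws, hyper = hyper_draws)
  })
}

post_normal_mean <- function(x, sd_x, prior_mean, prior_sd) {
  n <- length(x)
  prec <- n / sd_x^2 + 1 / prior_sd^2
  m <- (sum(x) / sd_x^2 + prior_mean / prior_sd^2) / prec
  stats::rnorm(1, m, sqrt(1 / prec))
}

mh_scale_sd <- function(x, mu, cur, scale, prior_sd, adapting, gam, target) {
  ll <- function(s) sum(stats::dnorm(x, mu, s, log = TRUE)) +
    stats::dnorm(s, 0, prior_sd, log = TRUE) + log(2)
  prop <- cur * exp(stats::rnorm(1, 0, scale))
  acc <- min(1, exp(ll(prop) - ll(cur) + log(prop) - log(cur)))
  if (stats::runif(1) < acc) cur <- prop
  if (adapting) scale <- exp(log(scale) + gam * (acc - target))
  list(value = cur, scale = scale)
}

# ---- internal: combine chains ---------------------------------------------

b3_collect <- function(chains, dat, basis, config, years_grid) {
  nC <- length(dat$countries)
  n_keep <- config$samples
  chain_id <- rep(seq_along(chains), each = n_keep)
  posteriors <- list()
  alpha_draws <- list()
  conv <- list()
  check_years <- intersect(c(1990, 2000, config$projection_year), years_grid)
  for (ci in seq_len(nC)) {
    draws <- do.call(rbind, lapply(chains, function(ch) ch$logq[[ci]]))
    alpha_draws[[ci]] <- do.call(rbind, lapply(chains, function(ch) ch$alpha[[ci]]))
    post <- q_posterior(dat$countries[ci], years_grid, draws, source = "b3",
                        last_obs_year = dat$cdat[[ci]]$last_obs)
    posteriors[[dat$countries[ci]]] <- post
    for (yy in check_years) {
      x <- draws[, match(yy, years_grid)]
      conv[[length(conv) + 1]] <- data.frame(
        country = dat$countries[ci], year = yy,
        rhat = split_rhat(x, chain_id), ess = ess_basic(x, chain_id))
    }
  }
  names(alpha_draws) <- dat$countries
  bias_draws <- do.call(rbind, lapply(chains, function(ch) ch$bias))
  if (length(dat$series)) {
    colnames(bias_draws) <- paste(rep(dat$series, each = 2), c("b0", "b1"), sep = ".")
  }
  omega_draws <- do.call(rbind, lapply(chains, function(ch) ch$omega))
  if (length(dat$omega_types)) colnames(omega_draws) <- dat$omega_types
  hyper_draws <- do.call(rbind, lapply(chains, function(ch) ch$hyper))
  colnames(hyper_draws) <- c("mu0", "tau0", "mu1", "tau1", "mu_lambda", "sigma_lambda")
  convergence <- do.call(rbind, conv)
  if (any(convergence$rhat >= 1.1, na.rm = TRUE)) {
    warning("split R-hat >= 1.1 for some quantities; inspect $convergence before use")
  }
  structure(
    list(posteriors = posteriors, alpha_draws = alpha_draws,
         bias_draws = bias_draws,
         lambda_draws = do.call(rbind, lapply(chains, function(ch) ch$lambda)),
         omega_draws = omega_draws, hyper_draws = hyper_draws,
         chain_id = chain_id, convergence = convergence,
         series = dat$series, basis = basis, config = config,
         years = years_grid),
    class = "b3_fit"
  )
}

#' Posterior trajectory container
#'
#' The common contract between the B3 model and the sparse-country
#' fallback: a draws-by-years matrix of log 10q15 plus metadata.
#'
#' @param country Country identifier.
#' @param years Integer years of the grid.
#' @param draws Matrix (draws by years) of log q.
#' @param source `"b3"` or `"sparse"`.
#' @param last_obs_year Last observation time feeding the fit (NA for
#'   sparse predictions).
#' @return Object of class `q_posterior`.
#' @export
q_posterior <- function(country, years, draws, source = "b3",
                        last_obs_year = NA_real_) {
  stopifnot(is.matrix(draws), ncol(draws) == length(years),
            all(is.finite(draws)))
  structure(list(country = country, years = as.integer(years), draws = draws,
                 source = source, last_obs_year = last_obs_year),
            class = "q_posterior")
}

#' @export
print.q_posterior <- function(x, ...) {
  cat(sprintf("q_posterior [%s] %s: %d draws, years %d-%d\n", x$source,
              x$country, nrow(x$draws), min(x$years), max(x$years)))
  invisible(x)
}

#' @export
print.b3_fit <- function(x, ...) {
  cat(sprintf("B3 fit: %d countries, %d draws (%d chains), years %d-%d\n",
              length(x$posteriors), nrow(x$bias_draws), x$config$chains,
              min(x$years), max(x$years)))
  cat(sprintf("max split R-hat %.3f\n", max(x$convergence$rhat, na.rm = TRUE)))
  invisible(x)
}

# split R-hat (each chain halved) and a basic ESS
split_rhat <- function(x, chain_id) {
  halves <- split(x, paste(chain_id, ave(seq_along(x), chain_id,
                                         FUN = function(i) i > mean(i))))
  m <- length(halves); n <- min(lengths(halves))
  if (n < 4) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars); B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(x, chain_id) {
  per <- vapply(split(x, chain_id), function(xc) {
    n <- length(xc)
    if (stats::var(xc) == 0) return(n)
    rho <- stats::acf(xc, lag.max = min(100, n - 2), plot = FALSE)$acf[-1]
    neg <- which(rho < 0)
    if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
    n / (1 + 2 * sum(rho))
  }, numeric(1))
  sum(per)
}

#' Extend a posterior trajectory to a later target year
#'
#' Evaluates the stored spline-coefficient draws on years up to
#' `target_year`; projections inherit the penalty process, so interval
#' width is non-decreasing beyond the last observation year.  Years already
#' on the grid are returned unchanged.
#'
#' @param fit A `b3_fit`.
#' @param target_year Calendar year, at most the end of the basis domain.
#' @return The `b3_fit` with posterior grids extended.
#' @export
extrapolate <- function(fit, target_year) {
  stopifnot(inherits(fit, "b3_fit"))
  if (target_year > fit$basis$domain[2] - 0.5) {
    stop("target_year lies beyond the spline basis domain")
  }
  if (target_year <= max(fit$years)) return(fit)
  new_years <- seq(min(fit$years), target_year)
  B_grid <- eval_basis(fit$basis, new_years + 0.5)
  for (cc in names(fit$posteriors)) {
    draws <- fit$alpha_draws[[cc]] %*% t(B_grid)
    fit$posteriors[[cc]] <- q_posterior(cc, new_years, draws, "b3",
                                        fit$posteriors[[cc]]$last_obs_year)
  }
  fit$years <- new_years
  fit
}

#' Reinsert crisis excess mortality into a fitted trend
#'
#' For each crisis event, every posterior draw's q in that country-year is
#' replaced by `1 - (1 - q)(1 - q_excess)`, with the excess probability
#' converted from excess deaths over band person-years.  The fit must have
#' been run with crisis-year observations excluded.
#'
#' @param fit A `b3_fit` (or a single `q_posterior`).
#' @param events Crisis-event table `country`, `year`, `excess_deaths`.
#' @param pop Population table (bands (15,5) and (20,5)).
#' @return The fit with adjusted draws.
#' @export
crisis_adjust <- function(fit, events, pop) {
  single <- inherits(fit, "q_posterior")
  posts <- if (single) stats::setNames(list(fit), fit$country) else fit$posteriors
  if (nrow(events)) for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    post <- posts[[ev$country]]
    if (is.null(post)) next
    j <- match(ev$year, post$years)
    if (is.na(j)) {
      warning(sprintf("crisis year %s outside estimate range for %s; skipped",
                      ev$year, ev$country))
      next
    }
    py <- band_person_years(pop, ev$country, ev$year)
    q_exc <- m_to_q(ev$excess_deaths / py, 10)
    post$draws[, j] <- log(1 - (1 - exp(post$draws[, j])) * (1 - q_exc))
    posts[[ev$country]] <- post
  }
  if (single) posts[[1]] else { fit$posteriors <- posts; fit }
}

#' Summarize posterior trajectories
#'
#' Pointwise medians and 90% uncertainty intervals (5th and 95th
#' percentiles of the draws) on the q scale.
#'
#' @param x A `q_posterior` or a `b3_fit` (all countries).
#' @param years Years to report (default: the full grid).
#' @return Data frame `country`, `year`, `median`, `lower`, `upper` (per 1).
#' @export
summarize_posterior <- function(x, years = NULL) {
  if (inherits(x, "b3_fit")) {
    return(do.call(rbind, lapply(x$posteriors, summarize_posterior, years = years)))
  }
  stopifnot(inherits(x, "q_posterior"))
  years <- years %||% x$years
  j <- match(years, x$years)
  if (anyNA(j)) stop("requested years outside the posterior grid")
  qs <- apply(exp(x$draws[, j, drop = FALSE]), 2, stats::quantile,
              probs = c(0.05, 0.5, 0.95), names = FALSE)
  out <- data.frame(country = x$country, year = years, median = qs[2, ],
                    lower = qs[1, ], upper = qs[3, ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
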