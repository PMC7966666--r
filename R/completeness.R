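#' Death-registration completeness by generalized growth balance
#'
#' The generalized growth balance (GGB) method compares the age
#' distribution of registered intercensal deaths with the age distributions
#' of two census enumerations.  In a closed population, for every open age
#' x+ the rate of entry into the open group minus its growth rate equals
#' its death rate; when only a fraction c of deaths is registered, the
#' observed partial death rates are too low by the factor 1/c, so the
#' points (partial death rate, entry rate - growth rate) fall on a line
#' with slope 1/c.  The line is fitted by orthogonal (total least squares)
#' regression, the standard choice in death-distribution methods.
#'
#' @name completeness
NULL

#' Simulate a stable population with incomplete death registration
#'
#' Generates the GGB inputs -- two census age distributions and intercensal
#' registered deaths in 5-year groups with an open interval -- from a Siler
#' mortality schedule and a stable age structure with constant growth.
#' Registered deaths are the true intercensal deaths thinned to the target
#' completeness, with optional Poisson noise.
#'
#' @param growth Stable population growth rate per year.
#' @param completeness True registration completeness in (0, 1].
#' @param t1,t2 Census dates (years).
#' @param size Total population at the first census.
#' @param open_age Start of the open age interval (default 85).
#' @param poisson_noise Draw registered deaths and census counts with
#'   Poisson noise (default TRUE; set FALSE for exact checks).
#' @param seed Integer seed (used only when `poisson_noise`).
#' @param siler Parameters of the Siler hazard
#'   `a1*exp(-b1*age) + a2 + a3*exp(b3*age)`.
#' @return List with data frames `census1`, `census2` (columns `age_start`,
#'   `age_width`, `count`), `deaths` (mean annual registered deaths by age
#'   group), and the generating `completeness`, `t1`, `t2`.
#' @export
simulate_stable_population <- function(growth = 0.02, completeness = 1,
                                       t1 = 2000, t2 = 2010, size = 5e5,
                                       open_age = 85, poisson_noise = TRUE,
                                       seed = 1,
                                       siler = c(a1 = 0.03, b1 = 1.1,
                                                 a2 = 5e-4, a3 = 4e-5,
                                                 b3 = 0.095)) {
  stopifnot(completeness > 0, completeness <= 1, t2 > t1)
  da <- 0.05                                         # fine grid: keeps the growth-balance identity tight
  ages <- seq(da / 2, 110 - da / 2, by = da)
  mx <- siler[["a1"]] * exp(-siler[["b1"]] * ages) + siler[["a2"]] +
    siler[["a3"]] * exp(siler[["b3"]] * ages)
  lx <- exp(-cumsum(c(0, mx[-length(mx)])) * da)     # survivors at each grid midpoint
  stable <- exp(-growth * ages) * lx * da            # person-years per grid cell
  stable <- stable / sum(stable)
  deaths1 <- stable * mx                             # annual deaths at census 1, per capita
  group <- 5 * (floor(ages) %/% 5)
  group[group > open_age] <- open_age
  agg <- function(x) as.numeric(tapply(x, group, sum))
  age_start <- sort(unique(group))
  n_grp <- length(age_start)
  c1 <- size * agg(stable)
  c2 <- c1 * exp(growth * (t2 - t1))
  d_mid <- size * agg(deaths1) * exp(growth * (t2 - t1) / 2) * completeness
  if (poisson_noise) {
    with_seed(seed, {
      c1 <- stats::rpois(n_grp, c1)
      c2 <- stats::rpois(n_grp, c2)
      d_mid <- stats::rpois(n_grp, d_mid)
    })
  }
  band <- data.frame(age_start = age_start,
                     age_width = c(rep(5L, n_grp - 1), NA_integer_))
  list(census1 = cbind(band, count = c1),
       census2 = cbind(band, count = c2),
       deaths = cbind(band, count = d_mid),
       completeness = completeness, t1 = t1, t2 = t2)
}

#' Fit the generalized growth balance model
#'
#' @param census1,census2 Data frames `age_start`, `count` in 5-year groups
#'   up to an open interval of at least 65+; the two censuses must share
#'   the same age groups.
#' @param deaths Data frame `age_start`, `count`: mean annual registered
#'   deaths over the intercensal period, same groups.
#' @param t1,t2 Census dates; `t2 > t1`.
#' @param age_range Open ages x for which the balance points x+ enter the
#'   fit (default `seq(15, 65, 5)`, targeting adult ages with >= 8 points).
#' @return Object of class `completeness_estimate`: list with `c`
#'   (completeness, clipped to (0, 1.5]), `intercept` (residual
#'   coverage-change term), `fit_points` (data frame of partial death rate
#'   vs entry-minus-growth rate by open age), `ages_used`, `period`.
#' @export
ggb_fit <- function(census1, census2, deaths, t1, t2,
                    age_range = seq(15, 65, 5)) {
  if (t2 <= t1) stop("t2 must exceed t1")
  ages <- census1$age_start
  if (!identical(ages, census2$age_start) || !identical(ages, deaths$age_start)) {
    stop("census and deaths tables must share identical age groups")
  }
  if (is.unsorted(ages, strictly = TRUE)) stop("age groups must be increasing")
  if (max(ages) < 65) stop("an open interval of at least 65+ is required")
  if (length(age_range) < 4) stop("the GGB fit needs at least 4 open-age points")
  if (all(deaths$count == 0)) stop("registered deaths are all zero; completeness is undefined")
  T <- t2 - t1
  census1$count <- as.numeric(census1$count)
  census2$count <- as.numeric(census2$count)
  deaths$count <- as.numeric(deaths$count)
  cum_from <- function(x, a) sum(x[ages >= a])
  pts <- lapply(age_range, function(a) {
    n1 <- cum_from(census1$count, a); n2 <- cum_from(census2$count, a)
    if (n1 <= 0 || n2 <= 0) stop(sprintf("zero census counts above age %d", a))
    ny <- T * sqrt(n1 * n2)                         # person-years in x+
    ent1 <- (census1$count[ages == a - 5] + census1$count[ages == a]) / 10
    ent2 <- (census2$count[ages == a - 5] + census2$count[ages == a]) / 10
    if (!length(ent1) || !length(ent2)) stop(sprintf("missing age group around %d", a))
    b <- sqrt(ent1 * ent2) / (ny / T)               # entry rate into x+
    r <- log(n2 / n1) / T                           # growth rate of x+
    d <- cum_from(deaths$count, a) / (ny / T)       # partial death rate
    c(age = a, d = d, bmr = b - r)
  })
  pts <- as.data.frame(do.call(rbind, pts))
  fit <- orthogonal_line(pts$d, pts$bmr)
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    stop("GGB fit degenerate: non-positive slope (check input data)")
  }
  structure(
    list(c = min(1 / fit$slope, 1.5), intercept = fit$intercept,
         fit_points = pts, ages_used = range(age_range),
         period = c(t1, t2)),
    class = "completeness_estimate"
  )
}

# orthogonal (total least squares / Deming with ratio 1) regression of y on x
orthogonal_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2); syy <- mean((y - my)^2); sxy <- mean((x - mx) * (y - my))
  if (abs(sxy) < .Machine$double.eps) stop("degenerate orthogonal regression")
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  list(slope = slope, intercept = my - slope * mx)
}

#' @export
print.completeness_estimate <- function(x, ...) {
  cat(sprintf("GGB completeness estimate: c = %.3f (intercept %.4f), ages %d+ to %d+, period %s-%s\n",
              x$c, x$intercept, x$ages_used[1], x$ages_used[2],
              x$period[1], x$period[2]))
  invisible(x)
}

#' Adjust a vital-registration series for incomplete death registration
#'
#' Registered death rates are divided by `min(c, 1)` before conversion back
#' to the band probability (equivalently, log q shifts by `-log(min(c, 1))`
#' for small q), the sampling SE is inflated by a completeness-uncertainty
#' term, and the source is relabelled `vr_incomplete` when `c < 0.95`.
#' Series with `c` below the inclusion threshold are flagged excluded
#' rather than adjusted, mirroring the selection of usable VR country-years.
#'
#' @param obs Observation table rows (VR rows are adjusted; others pass
#'   through untouched).
#' @param estimate A `completeness_estimate` from [ggb_fit()], or a bare
#'   numeric completeness.
#' @param c_se Standard error attributed to the completeness estimate on
#'   the log scale (default 0.05).
#' @param include_threshold Minimum completeness for a VR series to enter
#'   the likelihood (default 0.5).
#' @return The observation table with adjusted q, inflated `se_logq`,
#'   updated `source_type`, and exclusion flags where applicable.
#' @export
adjust_vr_series <- function(obs, estimate, c_se = 0.05,
                             include_threshold = 0.5) {
  cc <- if (inherits(estimate, "completeness_estimate")) estimate$c else estimate
  if (!is.numeric(cc) || cc <= 0 || cc > 1.5) stop("completeness must lie in (0, 1.5]")
  vr <- obs$source_type %in% c("vr_complete", "vr_incomplete")
  if (!any(vr)) return(obs)
  if (cc < include_threshold) {
    obs$excluded[vr] <- TRUE
    obs$exclusion_reason[vr] <- "completeness_below_threshold"
    return(obs)
  }
  c_eff <- min(cc, 1)
  n <- obs$age_width[vr]
  m_adj <- q_to_m(obs$q[vr], n) / c_eff
  obs$q[vr] <- m_to_q(m_adj, n)
  if (c_eff < 1) obs$se_logq[vr] <- sqrt(obs$se_logq[vr]^2 + c_se^2)
  obs$source_type[vr] <- if (cc < 0.95) "vr_incomplete" else obs$source_type[vr]
  obs
}
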