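#' Synthetic multi-country world with known youth-mortality truth
#'
#' The generator builds the test bed for the whole pipeline: smooth latent
#' trajectories of log 10q15 per country, an under-5 mortality series tied
#' to youth mortality through a log-quadratic link (so the plausibility
#' screen has an in-world reference relation), populations, and observation
#' series reproducing the error structure of each real-world source: vital
#' registration with under-registration, sibling-history surveys with a
#' recall bias that grows linearly with the retrospective period, census
#' household-death reports with underreporting, and sample registration
#' systems.  All generators are pure functions of their parameters and a
#' seed.
#'
#' @name synthetic_world
NULL

#' Default generation parameters for the synthetic world
#'
#' Levels are calibrated so that the world median 10q15 sits near 11 per
#' 1000 in 2019 with a mean decline of about 1.4 percent per year, and the
#' 5q15 share of 10q15 is near 0.46 -- the orders of magnitude of observed
#' global youth mortality.  Bias defaults: sibling survey level shifts with
#' SD 0.1 on the log scale and a recall-bias slope of -0.02 per year of
#' retrospective lag (SD 0.01), census underreporting factor 0.85, VR
#' completeness drawn from (0.55, 0.9) for incomplete-VR countries.
#'
#' @param ... Named overrides of any default element.
#' @return Named list of generation parameters.
#' @export
world_params <- function(...) {
  p <- list(
    years = 1985:2019,
    # latent trend: regional + country intercepts/slopes + smooth deviation
    region_level_mean = log(0.0154), region_level_sd = 0.35,
    country_level_sd = 0.30,
    region_slope_mean = -0.014, region_slope_sd = 0.006,
    country_slope_sd = 0.005,
    deviation_sd = 0.003,          # innovation SD of the integrated random walk
    center_year = 2000,
    # 5q15 / 10q15 ratio
    ratio_logit_mean = -0.16, ratio_logit_sd = 0.15,
    ratio_slope_mean = -0.003, ratio_slope_sd = 0.002,
    ratio_bounds = c(0.2, 0.8),
    # log-quadratic link from log 10q15 to log 5q0 (+ country-level noise)
    link_a0 = 2.0, link_a1 = 1.18, link_a2 = 0.04,
    link_country_sd = 0.13, link_year_sd = 0.03,
    # populations (person-years per 5-year band)
    pop_meanlog = log(2e5), pop_sdlog = 0.8, pop_growth = 0.01,
    # observation-process parameters
    bias = bias_params(),
    vr_last_year = 2017,
    srs_fraction = 0.05,
    sibling_window = 5, sibling_horizon = 15,
    sibling_effective_n = 6000, design_effect = 1.5,
    # crises: excess deaths as a fraction of band person-years
    crisis_excess_rate = 0.002
  )
  dots <- list(...)
  p[names(dots)] <- dots
  p
}

#' Bias parameters of the synthetic observation processes
#'
#' @param sibling_level_bias_sd SD of the per-survey level shift on log q.
#' @param sibling_slope_mean,sibling_slope_sd Mean and SD of the per-survey
#'   recall-bias slope, per year of retrospective lag (negative mean: deaths
#'   further in the past are increasingly omitted).
#' @param census_underreport_factor Multiplicative thinning of census
#'   household deaths in (0, 1].
#' @param vr_completeness_range Interval in (0, 1] from which the true
#'   registration completeness of incomplete-VR countries is drawn.
#' @param nonsampling_sd_by_source Named vector of extra non-sampling noise
#'   SDs on log q, by source type.
#' @return Named list of bias parameters.
#' @export
bias_params <- function(sibling_level_bias_sd = 0.10,
                        sibling_slope_mean = -0.02,
                        sibling_slope_sd = 0.01,
                        census_underreport_factor = 0.85,
                        vr_completeness_range = c(0.55, 0.90),
                        nonsampling_sd_by_source = c(vr_complete = 0,
                                                     vr_incomplete = 0.02,
                                                     srs = 0.025,
                                                     sibling = 0.05,
                                                     census = 0.05)) {
  stopifnot(sibling_level_bias_sd >= 0, sibling_slope_sd >= 0,
            census_underreport_factor > 0, census_underreport_factor <= 1,
            all(vr_completeness_range > 0), all(vr_completeness_range <= 1),
            all(nonsampling_sd_by_source >= 0))
  list(sibling_level_bias_sd = sibling_level_bias_sd,
       sibling_slope_mean = sibling_slope_mean,
       sibling_slope_sd = sibling_slope_sd,
       census_underreport_factor = census_underreport_factor,
       vr_completeness_range = vr_completeness_range,
       nonsampling_sd_by_source = nonsampling_sd_by_source)
}

#' Generate true mortality trajectories for a synthetic world
#'
#' Each country's log 10q15 path is a regional intercept plus a country
#' intercept, a linear slope, and a smooth deviation (an integrated random
#' walk, centred and detrended so it carries curvature only).  log 5q0 is
#' produced from log 10q15 through a log-quadratic link with country-level
#' noise, so the quality screen's reference relation exists in-world.
#'
#' @param n_countries Number of countries (>= 1).
#' @param n_regions Number of regions.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param params Parameter list from [world_params()].
#' @return Data frame of class `true_trajectories` with one row per
#'   country-year: `country`, `region`, `year`, `q15_24_true`, `ratio_true`
#'   (5q15 share), `q15_19_true`, `q5_0_true`, `crisis` (logical).
#' @export
generate_truth <- function(n_countries = 20, n_regions = 4, seed = 1,
                           params = world_params()) {
  if (n_countries < 1) stop("n_countries must be >= 1")
  if (n_regions < 1 || n_regions > n_countries) {
    stop("n_regions must lie in [1, n_countries]")
  }
  years <- params$years
  ny <- length(years)
  with_seed(seed, {
    region_of <- rep_len(seq_len(n_regions), n_countries)
    a_g <- stats::rnorm(n_regions, params$region_level_mean, params$region_level_sd)
    b_g <- stats::rnorm(n_regions, params$region_slope_mean, params$region_slope_sd)
    out <- vector("list", n_countries)
    for (c_i in seq_len(n_countries)) {
      g <- region_of[c_i]
      a_c <- stats::rnorm(1, 0, params$country_level_sd)
      b_c <- stats::rnorm(1, 0, params$country_slope_sd)
      tc <- years - params$center_year
      dev <- integrated_rw(ny, params$deviation_sd)
      logq <- a_g[g] + a_c + (b_g[g] + b_c) * tc + dev
      logq <- pmin(logq, log(0.45))
      r0 <- stats::rnorm(1, params$ratio_logit_mean, params$ratio_logit_sd)
      r_sl <- stats::rnorm(1, params$ratio_slope_mean, params$ratio_slope_sd)
      ratio <- stats::plogis(r0 + r_sl * tc)
      ratio <- pmin(pmax(ratio, params$ratio_bounds[1]), params$ratio_bounds[2])
      eta_c <- stats::rnorm(1, 0, params$link_country_sd)
      logq5 <- params$link_a0 + params$link_a1 * logq +
        params$link_a2 * logq^2 + eta_c +
        stats::rnorm(ny, 0, params$link_year_sd)
      logq5 <- pmin(logq5, log(0.45))
      q <- exp(logq)
      out[[c_i]] <- data.frame(
        country = sprintf("C%02d", c_i),
        region = sprintf("R%d", g),
        year = years,
        q15_24_true = q,
        ratio_true = ratio,
        q15_19_true = ratio * q,
        q5_0_true = exp(logq5),
        crisis = FALSE,
        stringsAsFactors = FALSE
      )
    }
    truth <- do.call(rbind, out)
    class(truth) <- c("true_trajectories", "data.frame")
    truth
  })
}

# integrated random walk, centred and detrended: pure smooth curvature
integrated_rw <- function(n, innovation_sd) {
  if (innovation_sd <= 0) return(rep(0, n))
  s <- cumsum(cumsum(stats::rnorm(n, 0, innovation_sd)))
  t <- seq_len(n)
  stats::residuals(stats::lm.fit(cbind(1, t), s))
}

#' Generate synthetic population person-years
#'
#' Constant-growth populations per country for the age bands (0,5), (15,5)
#' and (20,5); person-years approximate mid-year population times one year.
#'
#' @inheritParams generate_truth
#' @param truth Trajectories from [generate_truth()].
#' @return Data frame `country`, `year`, `age_start`, `age_width`,
#'   `person_years`.
#' @export
generate_population <- function(truth, seed = 1, params = world_params()) {
  countries <- unique(truth$country)
  years <- sort(unique(truth$year))
  with_seed(child_seed(seed, 101), {
    base <- stats::rlnorm(length(countries), params$pop_meanlog, params$pop_sdlog)
    grid <- expand.grid(country = countries, year = years,
                        age_start = c(0, 15, 20), stringsAsFactors = FALSE)
    grid <- grid[order(grid$country, grid$year, grid$age_start), ]
    b <- base[match(grid$country, countries)]
    growth <- exp(params$pop_growth * (grid$year - min(years)))
    band_scale <- c(`0` = 1.15, `15` = 1, `20` = 0.95)
    grid$age_width <- 5L
    grid$person_years <- b * growth * band_scale[as.character(grid$age_start)]
    rownames(grid) <- NULL
    grid
  })
}

band_person_years <- function(pop, country, year, age_start = c(15, 20)) {
  sel <- pop$country == country & pop$year == year & pop$age_start %in% age_start
  if (!any(sel)) stop(sprintf("no population for %s in %s", country, year))
  sum(pop$person_years[sel])
}

#' Simulate vital-registration observations of 10q15
#'
#' True deaths are binomial draws from the annual hazard implied by the
#' band probability; registered deaths are a binomial thinning by the
#' registration completeness.  The observed q is recovered through the
#' abridged life-table conversion, and the sampling SE of log q comes from
#' the binomial variance of the registered count.
#'
#' @param traj Trajectory rows of one country (subset of [generate_truth()]).
#' @param pop Population table from [generate_population()].
#' @param completeness Registration completeness in (0, 1]; a scalar or a
#'   vector along the simulated years.
#' @param seed Integer seed.
#' @param years Years to register (default: all trajectory years).
#' @param source_type Forced source label; by default `vr_complete` iff
#'   `completeness` is identically 1, else `vr_incomplete`.
#' @param sample_fraction Fraction of the population observed (1 for VR;
#'   below 1 emulates a sample registration system).
#' @param nonsampling_sd Extra non-sampling noise SD on log q.
#' @return Observation table rows (see [validate_observations()]).
#' @export
simulate_vr <- function(traj, pop, completeness = 1, seed = 1,
                        years = NULL, source_type = NULL,
                        sample_fraction = 1, nonsampling_sd = 0) {
  stopifnot(all(completeness > 0), all(completeness <= 1))
  country <- traj$country[1]
  years <- years %||% traj$year
  comp <- rep_len(completeness, length(years))
  if (is.null(source_type)) {
    source_type <- if (all(comp == 1) && sample_fraction == 1) "vr_complete" else "vr_incomplete"
  }
  with_seed(seed, {
    rows <- lapply(seq_along(years), function(i) {
      yr <- years[i]
      q_true <- traj$q15_24_true[traj$year == yr]
      if (!length(q_true)) return(NULL)
      n_band <- band_person_years(pop, country, yr) * sample_fraction
      n <- round(n_band)
      if (n < 1) return(NULL)
      m <- q_to_m(q_true, 10)
      p_ann <- 1 - exp(-m)
      d_true <- stats::rbinom(1, n, p_ann)
      d_reg <- stats::rbinom(1, d_true, comp[i])
      if (d_reg < 1) return(NULL)
      p_hat <- d_reg / n
      m_hat <- -log(1 - p_hat)
      q_obs <- m_to_q(m_hat, 10)
      se <- sqrt((1 - p_hat) / d_reg)
      if (nonsampling_sd > 0) q_obs <- q_obs * exp(stats::rnorm(1, 0, nonsampling_sd))
      data.frame(country = country,
                 series_id = paste0(country, "-", source_type),
                 source_type = source_type,
                 ref_time = yr + 0.5, collection_time = yr + 0.5,
                 age_start = 15L, age_width = 10L,
                 q = q_obs, se_logq = se,
                 excluded = FALSE, exclusion_reason = NA_character_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows) %||% empty_observations()
  })
}

empty_observations <- function() {
  data.frame(country = character(), series_id = character(),
             source_type = character(), ref_time = numeric(),
             collection_time = numeric(), age_start = integer(),
             age_width = integer(), q = numeric(), se_logq = numeric(),
             excluded = logical(), exclusion_reason = character(),
             stringsAsFactors = FALSE)
}

#' Simulate a sibling-history survey series
#'
#' One observation per retrospective window (default 5-year windows over a
#' 15-year recall horizon).  On the log scale the observation equals the
#' truth at the window midpoint plus a per-survey level bias b0, a recall
#' bias b1 times the retrospective lag, and sampling plus non-sampling
#' noise.  Paired under-5 observations from the same survey's birth
#' histories are emitted as age band (0, 5) rows so the quality screen can
#' evaluate the survey.
#'
#' @param traj One country's trajectory rows.
#' @param survey_year Field date (decimal year).
#' @param bias [bias_params()] list.
#' @param effective_n Effective number of sibling exposures per window.
#' @param seed Integer seed.
#' @param window Window width in years (default 5).
#' @param horizon Recall horizon in years (default 15).
#' @param design_effect Variance inflation for complex survey design.
#' @return Observation table rows, bands (15, 10) and (0, 5), with
#'   attributes `b0` and `b1` recording the generating bias of this survey.
#' @export
simulate_sibling_survey <- function(traj, survey_year, bias = bias_params(),
                                    effective_n = 6000, seed = 1,
                                    window = 5, horizon = 15,
                                    design_effect = 1.5) {
  country <- traj$country[1]
  if (survey_year > max(traj$year) + 1.5 || survey_year < min(traj$year)) {
    stop("survey_year must fall within (or just after) the trajectory years")
  }
  mids <- survey_year - seq(window / 2, horizon - window / 2, by = window)
  keep <- mids >= min(traj$year)
  if (!all(keep)) {
    warning("recall windows before trajectory start were truncated")
    mids <- mids[keep]
  }
  with_seed(seed, {
    b0 <- stats::rnorm(1, 0, bias$sibling_level_bias_sd)
    b1 <- stats::rnorm(1, bias$sibling_slope_mean, bias$sibling_slope_sd)
    ns_sd <- bias$nonsampling_sd_by_source[["sibling"]]
    sid <- sprintf("%s-sib%s", country, round(survey_year))
    rows <- lapply(mids, function(mid) {
      lag <- survey_year - mid
      q_true <- exp(interp_series(traj$year + 0.5, log(traj$q15_24_true), mid))
      q5_true <- exp(interp_series(traj$year + 0.5, log(traj$q5_0_true), mid))
      se <- sqrt(design_effect * (1 - q_true) / (effective_n * q_true))
      se5 <- sqrt(design_effect * (1 - q5_true) / (effective_n * q5_true))
      logq_obs <- log(q_true) + b0 + b1 * lag +
        stats::rnorm(1, 0, sqrt(se^2 + ns_sd^2))
      logq5_obs <- log(q5_true) + stats::rnorm(1, 0, se5)
      data.frame(country = country, series_id = sid, source_type = "sibling",
                 ref_time = mid, collection_time = survey_year,
                 age_start = c(15L, 0L), age_width = c(10L, 5L),
                 q = pmin(exp(c(logq_obs, logq5_obs)), 0.95),
                 se_logq = c(se, se5),
                 excluded = FALSE, exclusion_reason = NA_character_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "b0") <- b0
    attr(out, "b1") <- b1
    out
  })
}

#' Simulate census household-death observations
#'
#' Household deaths in the 12 months preceding the census are binomial
#' draws thinned by the underreporting factor; the implied central rate is
#' converted to the band probability through the abridged life table.  A
#' paired under-5 observation is produced the same way.
#'
#' @param traj One country's trajectory rows.
#' @param pop Population table.
#' @param census_year Census field date (calendar year).
#' @param underreport_factor Multiplicative reporting completeness in (0, 1]
#'   applied to deaths at ages 15-24 (under-5 deaths are left unthinned so
#'   the age-pattern screen sees the distortion).
#' @param seed Integer seed.
#' @return Observation rows with bands (15, 10) and (0, 5);
#'   `ref_time = census_year - 0.5`.
#' @export
simulate_census <- function(traj, pop, census_year, underreport_factor = 1,
                            seed = 1) {
  stopifnot(underreport_factor > 0, underreport_factor <= 1)
  country <- traj$country[1]
  yr <- floor(census_year - 0.5)
  q_true <- exp(interp_series(traj$year + 0.5, log(traj$q15_24_true), census_year - 0.5))
  q5_true <- exp(interp_series(traj$year + 0.5, log(traj$q5_0_true), census_year - 0.5))
  n_youth <- round(band_person_years(pop, country, yr))
  n_child <- round(band_person_years(pop, country, yr, age_start = 0))
  with_seed(seed, {
    sid <- sprintf("%s-cen%s", country, round(census_year))
    p_y <- 1 - exp(-q_to_m(q_true, 10))
    p_c <- 1 - exp(-q_to_m(q5_true, 5))
    d_y <- stats::rbinom(1, stats::rbinom(1, n_youth, p_y), underreport_factor)
    d_c <- stats::rbinom(1, n_child, p_c)
    if (d_y < 1 || d_c < 1) return(empty_observations())
    q_obs <- m_to_q(d_y / n_youth, 10)
    q5_obs <- m_to_q(d_c / n_child, 5)
    data.frame(country = country, series_id = sid, source_type = "census",
               ref_time = census_year - 0.5, collection_time = census_year,
               age_start = c(15L, 0L), age_width = c(10L, 5L),
               q = c(q_obs, q5_obs),
               se_logq = c(sqrt((1 - d_y / n_youth) / d_y),
                           sqrt((1 - d_c / n_child) / d_c)),
               excluded = FALSE, exclusion_reason = NA_character_,
               stringsAsFactors = FALSE)
  })
}

#' Overlay crisis-year excess mortality on true trajectories
#'
#' Crisis-year q is replaced by \eqn{1-(1-q)(1-q_{excess})} where the
#' excess probability comes from excess deaths over band person-years via
#' the rate-to-probability conversion.  Years already flagged as crises
#' cannot be hit twice.
#'
#' @param truth Trajectories from [generate_truth()].
#' @param events Data frame `country`, `year`, `age_start`, `age_width`,
#'   `excess_deaths`.
#' @param pop Population table (for person-years).
#' @return `truth` with spiked q and `crisis` flags set.
#' @export
apply_crisis <- function(truth, events, pop) {
  if (!nrow(events)) return(truth)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    sel <- truth$country == ev$country & truth$year == ev$year
    if (!any(sel)) stop(sprintf("crisis event references unknown country-year %s %s",
                                ev$country, ev$year))
    if (any(truth$crisis[sel])) {
      stop(sprintf("crisis already applied to %s %s; reapplication is not allowed",
                   ev$country, ev$year))
    }
    py <- band_person_years(pop, ev$country, ev$year)
    if (ev$excess_deaths < 0 || ev$excess_deaths > 0.2 * py) {
      stop("excess_deaths must lie in [0, 0.2 x person-years]")
    }
    q_exc <- m_to_q(ev$excess_deaths / py, 10)
    truth$q15_24_true[sel] <- 1 - (1 - truth$q15_24_true[sel]) * (1 - q_exc)
    truth$q15_19_true[sel] <- truth$ratio_true[sel] * truth$q15_24_true[sel]
    truth$crisis[sel] <- TRUE
  }
  truth
}

#' Simulate a complete synthetic world
#'
#' Builds truth, populations, crisis events and a mixed portfolio of
#' observation series.  Countries cycle through five data profiles:
#' complete VR; incomplete VR plus a survey and a census; survey-and-census
#' only; a sample registration system; and complete VR ending early plus
#' recent surveys.  Two countries receive a crisis year each.
#'
#' @param n_countries Number of countries (default 20).
#' @param n_regions Number of regions (default 4).
#' @param seed Integer seed.
#' @param params [world_params()] list.
#' @param with_crises Add crisis events (default TRUE).
#' @return List of class `synthetic_world`: `truth`, `population`,
#'   `observations`, `events`, `region_map`, `true_completeness` (named by
#'   country, NA where no VR), `survey_bias` (data frame of generating b0,
#'   b1 per survey series), `params`, `seed`.
#' @export
simulate_world <- function(n_countries = 20, n_regions = 4, seed = 1,
                           params = world_params(), with_crises = TRUE) {
  truth <- generate_truth(n_countries, n_regions, seed, params)
  pop <- generate_population(truth, seed, params)
  countries <- unique(truth$country)
  events <- data.frame(country = character(), year = integer(),
                       age_start = integer(), age_width = integer(),
                       excess_deaths = numeric(), stringsAsFactors = FALSE)
  if (with_crises && n_countries >= 3) {
    crisis_countries <- countries[c(3, min(10, n_countries))]
    crisis_years <- c(1994L, 2010L)[seq_along(unique(crisis_countries))]
    crisis_countries <- unique(crisis_countries)
    events <- do.call(rbind, lapply(seq_along(crisis_countries), function(i) {
      py <- band_person_years(pop, crisis_countries[i], crisis_years[i])
      data.frame(country = crisis_countries[i], year = crisis_years[i],
                 age_start = 15L, age_width = 10L,
                 excess_deaths = params$crisis_excess_rate * py,
                 stringsAsFactors = FALSE)
    }))
    truth <- apply_crisis(truth, events, pop)
  }
  profiles <- rep_len(c("vr_complete", "vr_incomplete", "survey_only",
                        "srs", "vr_plus_survey"), n_countries)
  comp <- stats::setNames(rep(NA_real_, n_countries), countries)
  obs_list <- list()
  bias_rows <- list()
  add_survey <- function(tr, yr, sd) {
    s <- simulate_sibling_survey(tr, yr, params$bias,
                                 params$sibling_effective_n, sd,
                                 params$sibling_window, params$sibling_horizon,
                                 params$design_effect)
    bias_rows[[length(bias_rows) + 1]] <<- data.frame(
      country = tr$country[1], series_id = s$series_id[1],
      b0 = attr(s, "b0"), b1 = attr(s, "b1"), stringsAsFactors = FALSE)
    s
  }
  with_seed(child_seed(seed, 77), {
    comp_draws <- stats::runif(n_countries, params$bias$vr_completeness_range[1],
                               params$bias$vr_completeness_range[2])
  })
  for (ci in seq_len(n_countries)) {
    tr <- truth[truth$country == countries[ci], ]
    sd0 <- child_seed(seed, 1000 + ci)
    ns <- params$bias$nonsampling_sd_by_source
    obs_list[[length(obs_list) + 1]] <- switch(
      profiles[ci],
      vr_complete = {
        comp[ci] <- 1
        simulate_vr(tr, pop, 1, sd0, years = min(tr$year):params$vr_last_year)
      },
      vr_incomplete = {
        comp[ci] <- comp_draws[ci]
        rbind(
          simulate_vr(tr, pop, comp[ci], sd0,
                      years = min(tr$year):(params$vr_last_year - 1),
                      nonsampling_sd = ns[["vr_incomplete"]]),
          add_survey(tr, 2014.5, child_seed(sd0, 1)),
          simulate_census(tr, pop, 2010, params$bias$census_underreport_factor,
                          child_seed(sd0, 2))
        )
      },
      survey_only = rbind(
        add_survey(tr, 2000.5, child_seed(sd0, 1)),
        add_survey(tr, 2007.5, child_seed(sd0, 2)),
        add_survey(tr, 2014.5, child_seed(sd0, 3)),
        simulate_census(tr, pop, 2005, params$bias$census_underreport_factor,
                        child_seed(sd0, 4)),
        simulate_census(tr, pop, 2015, params$bias$census_underreport_factor,
                        child_seed(sd0, 5))
      ),
      srs = simulate_vr(tr, pop, 1, sd0, years = 1993:params$vr_last_year,
                        source_type = "srs",
                        sample_fraction = params$srs_fraction,
                        nonsampling_sd = ns[["srs"]]),
      vr_plus_survey = rbind(
        simulate_vr(tr, pop, 1, sd0, years = min(tr$year):2010),
        add_survey(tr, 2005.5, child_seed(sd0, 1)),
        add_survey(tr, 2015.5, child_seed(sd0, 2))
      )
    )
  }
  obs <- do.call(rbind, obs_list)
  rownames(obs) <- NULL
  validate_observations(obs)
  structure(
    list(truth = truth, population = pop, observations = obs,
         events = events,
         region_map = unique(truth[, c("country", "region")]),
         true_completeness = comp,
         survey_bias = do.call(rbind, bias_rows) %||%
           data.frame(country = character(), series_id = character(),
                      b0 = numeric(), b1 = numeric()),
         profiles = stats::setNames(profiles, countries),
         params = params, seed = seed),
    class = "synthetic_world"
  )
}
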