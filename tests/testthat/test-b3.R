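# small single-country worlds keep these sampler tests fast; the full
# 20-country study conditions are exercised in the acceptance suite

vr_country <- function(seed = 21, n_countries = 4) {
  w <- simulate_world(n_countries, 2, seed = seed, with_crises = FALSE)
  list(world = w,
       obs = w$observations[w$observations$country == "C01", ])  # complete VR
}

test_that("same seed gives identical draws; different seed does not", {
  d <- vr_country()
  f1 <- fit_b3(d$obs, config = quick_b3(3))
  f2 <- fit_b3(d$obs, config = quick_b3(3))
  expect_identical(f1$posteriors[["C01"]]$draws, f2$posteriors[["C01"]]$draws)
  f3 <- fit_b3(d$obs, config = quick_b3(4))
  expect_false(identical(f1$posteriors[["C01"]]$draws,
                         f3$posteriors[["C01"]]$draws))
})

test_that("with dense precise VR the fit tracks the observations", {
  d <- vr_country()
  fit <- fit_b3(d$obs, config = quick_b3(5))
  s <- summarize_posterior(fit$posteriors[["C01"]])
  post_sd <- apply(fit$posteriors[["C01"]]$draws, 2, sd)
  for (i in seq_len(nrow(d$obs))) {
    j <- match(floor(d$obs$ref_time[i]), s$year)
    z <- abs(log(d$obs$q[i]) - log(s$median[j])) /
      sqrt(post_sd[j]^2 + d$obs$se_logq[i]^2)
    expect_lt(z, 3)
  }
  expect_lt(max(fit$convergence$rhat, na.rm = TRUE), 1.1)
})

test_that("the error multiplier acts on the log scale: doubling q shifts draws by log 2", {
  d <- vr_country()
  f1 <- fit_b3(d$obs, config = quick_b3(6))
  obs2 <- d$obs; obs2$q <- obs2$q * 2
  f2 <- fit_b3(obs2, config = quick_b3(6))
  expect_equal(f2$posteriors[["C01"]]$draws,
               f1$posteriors[["C01"]]$draws + log(2), tolerance = 1e-9)
})

test_that("shifting the calendar shifts the estimates correspondingly", {
  d <- vr_country()
  cfg <- quick_b3(8)
  f1 <- fit_b3(d$obs, config = cfg)
  obs_s <- d$obs
  obs_s$ref_time <- obs_s$ref_time + 7
  obs_s$collection_time <- obs_s$collection_time + 7
  cfg2 <- cfg; cfg2$projection_year <- cfg$projection_year + 7
  f2 <- fit_b3(obs_s, config = cfg2)
  expect_equal(f2$years, f1$years + 7)
  expect_equal(f2$posteriors[["C01"]]$draws, f1$posteriors[["C01"]]$draws,
               tolerance = 1e-9)
})

test_that("a survey's level bias is identified against overlapping complete VR", {
  covered <- vapply(1:8, function(r) {
    w <- simulate_world(2, 1, seed = 300 + r, with_crises = FALSE)
    tr <- w$truth[w$truth$country == "C01", ]
    vr <- w$observations[w$observations$country == "C01", ]
    sib <- simulate_sibling_survey(tr, 2014.5, bias_params(
      sibling_level_bias_sd = 0, sibling_slope_mean = 0, sibling_slope_sd = 0),
      effective_n = 30000, seed = 400 + r)
    sib$q[sib$age_start == 15] <- sib$q[sib$age_start == 15] * exp(-0.25)
    fit <- fit_b3(rbind(vr, sib), config = quick_b3(500 + r))
    b0 <- fit$bias_draws[, paste0(sib$series_id[1], ".b0")]
    ci <- quantile(b0, c(0.05, 0.95))
    ci[1] <= -0.25 && -0.25 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 6)
})

test_that("projection uncertainty does not shrink beyond the data and respects the domain", {
  w <- simulate_world(4, 2, seed = 31, with_crises = FALSE)
  obs <- w$observations[w$observations$country == "C01" &
                          w$observations$ref_time < 2012, ]
  cfg <- quick_b3(9); cfg$projection_year <- 2017
  fit <- fit_b3(obs, config = cfg)
  s <- summarize_posterior(fit$posteriors[["C01"]])
  width <- log(s$upper) - log(s$lower)
  j <- which(s$year >= 2011)
  expect_true(all(diff(width[j]) > -1e-6))
  expect_error(extrapolate(fit, 2100), "domain")
  # extending within the domain appends years
  ext <- extrapolate(fit, max(fit$years) + 1)
  expect_equal(max(ext$years), max(fit$years) + 1)
  expect_equal(ext$posteriors[["C01"]]$draws[, seq_along(fit$years)],
               fit$posteriors[["C01"]]$draws)
})

test_that("noiseless log-linear data project along the line", {
  years <- 1985:2012
  a <- -4.1; b <- -0.015
  obs <- data.frame(
    country = "L", series_id = "L-vr", source_type = "vr_complete",
    ref_time = years + 0.5, collection_time = years + 0.5,
    age_start = 15L, age_width = 10L,
    q = exp(a + b * (years + 0.5 - 2000)), se_logq = 0.005,
    excluded = FALSE, exclusion_reason = NA_character_)
  fit <- fit_b3(obs, config = quick_b3(10))
  s <- summarize_posterior(fit$posteriors[["L"]], 2013:2019)
  expect_equal(log(s$median), a + b * (2013:2019 + 0.5 - 2000), tolerance = 0.03)
})

test_that("crisis reinsertion shifts draws by the exact excess and keeps widths", {
  w <- simulate_world(4, 2, seed = 33, with_crises = FALSE)
  obs <- w$observations[w$observations$country == "C01", ]
  fit <- fit_b3(obs, config = quick_b3(11))
  py <- sum(w$population$person_years[w$population$country == "C01" &
                                        w$population$year == 2005 &
                                        w$population$age_start %in% c(15, 20)])
  ev <- data.frame(country = "C01", year = 2005, excess_deaths = 0.01 * py)
  adj <- crisis_adjust(fit, ev, w$population)
  j <- match(2005, fit$years)
  q0 <- exp(fit$posteriors[["C01"]]$draws[, j])
  q_exc <- m_to_q(0.01, 10)
  expect_equal(exp(adj$posteriors[["C01"]]$draws[, j]),
               1 - (1 - q0) * (1 - q_exc), tolerance = 1e-10)
  # other years untouched; log-survival offset keeps that year's UI width
  expect_equal(adj$posteriors[["C01"]]$draws[, -j],
               fit$posteriors[["C01"]]$draws[, -j])
  w0 <- diff(quantile(log(1 - q0), c(0.05, 0.95)))
  w1 <- diff(quantile(log(1 - exp(adj$posteriors[["C01"]]$draws[, j])), c(0.05, 0.95)))
  expect_equal(unname(w1), unname(w0), tolerance = 1e-10)
  # zero excess is the identity
  ev0 <- ev; ev0$excess_deaths <- 0
  adj0 <- crisis_adjust(fit, ev0, w$population)
  expect_equal(adj0$posteriors[["C01"]]$draws, fit$posteriors[["C01"]]$draws)
  # out-of-range years warn and skip
  ev_far <- ev; ev_far$year <- 1902
  expect_warning(crisis_adjust(fit, ev_far, w$population), "skipped")
})

test_that("posterior summaries match an independent quantile computation", {
  set.seed(12)
  draws <- matrix(rnorm(500 * 3, mean = log(0.01), sd = 0.2), 500, 3)
  post <- q_posterior("Z", 2000:2002, draws)
  s <- summarize_posterior(post)
  for (j in 1:3) {
    srt <- sort(exp(draws[, j]))
    # type-7 quantile, computed by hand
    for (k in seq_along(c(0.05, 0.5, 0.95))) {
      p <- c(0.05, 0.5, 0.95)[k]
      h <- (length(srt) - 1) * p
      manual <- srt[floor(h) + 1] + (h - floor(h)) *
        (srt[min(floor(h) + 2, length(srt))] - srt[floor(h) + 1])
      expect_equal(c(s$lower[j], s$median[j], s$upper[j])[k], manual,
                   tolerance = 1e-12)
    }
  }
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
  const <- q_posterior("Z", 2000:2001, matrix(log(0.02), 100, 2))
  sc <- summarize_posterior(const)
  expect_equal(sc$lower, sc$upper)
})

test_that("countries below the data threshold are refused by the spline model", {
  w <- small_world()
  obs <- w$observations[w$observations$country == "C01", ][1:3, ]
  expect_error(fit_b3(obs), "sparse")
})
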