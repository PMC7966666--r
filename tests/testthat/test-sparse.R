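sparse_obs <- function(n, span) {
  data.frame(country = "S", series_id = "S-x", source_type = "srs",
             ref_time = seq(2000, 2000 + span, length.out = n),
             collection_time = seq(2000, 2000 + span, length.out = n),
             age_start = 15L, age_width = 10L, q = 0.01, se_logq = 0.05,
             excluded = FALSE, exclusion_reason = NA_character_)
}

test_that("the sparsity rule matches its boundary cases", {
  expect_true(is_sparse(sparse_obs(3, 20)))    # too few points
  expect_true(is_sparse(sparse_obs(4, 9.9)))   # too short a span
  expect_false(is_sparse(sparse_obs(4, 10)))   # exactly at the rule
  # excluded rows do not count
  o <- sparse_obs(5, 20); o$excluded[1:2] <- TRUE
  expect_true(is_sparse(o))
})

sim_mixed_world <- function(n, seed, sd_int = 0.15, sd_slope = 0.1,
                            sd_resid = 0.15, slope = 0.9, n_regions = 6) {
  set.seed(seed)
  regions <- paste0("R", seq_len(n_regions))
  u0 <- setNames(rnorm(n_regions, 0, sd_int), regions)
  u1 <- setNames(rnorm(n_regions, 0, sd_slope), regions)
  reg <- sample(regions, n, TRUE)
  x <- runif(n, log(0.005), log(0.15))
  y <- -1.2 + slope * x + u0[reg] + u1[reg] * x + rnorm(n, 0, sd_resid)
  data.frame(logq = y, logu5mr = x, region = reg)
}

test_that("the mixed model recovers the fixed slope and handles degeneracies", {
  pairs <- sim_mixed_world(3000, seed = 5)
  fit <- fit_mixed(pairs)
  expect_equal(unname(fit$fixed["slope"]), 0.9, tolerance = 0.05)
  expect_false(fit$ols_fallback)
  expect_true(all(fit$var_components[c("var_intercept", "var_slope",
                                       "var_residual")] >= 0))
  expect_lte(abs(fit$var_components[["covariance"]]),
             sqrt(fit$var_components[["var_intercept"]] *
                    fit$var_components[["var_slope"]]) + 1e-12)
  # single region: OLS fallback with warning
  one <- pairs; one$region <- "R1"
  expect_warning(f_ols <- fit_mixed(one), "OLS")
  expect_true(f_ols$ols_fallback)
  # no region variance in truth: estimated region SDs shrink
  flat <- sim_mixed_world(2000, seed = 6, sd_int = 0, sd_slope = 0)
  f_flat <- fit_mixed(flat)
  expect_lt(sqrt(f_flat$var_components[["var_intercept"]]), 0.05)
  expect_lt(sqrt(f_flat$var_components[["var_slope"]]), 0.05)
  expect_error(fit_mixed(pairs[1:5, ]), "10 training pairs")
})

test_that("sparse predictions share the posterior contract and widen off-support", {
  pairs <- sim_mixed_world(2000, seed = 7)
  fit <- fit_mixed(pairs)
  u5 <- data.frame(year = 2000:2005, u5mr = seq(0.05, 0.04, length.out = 6))
  p_seen <- predict_sparse(u5, "R1", fit, country = "S1", seed = 2)
  p_unseen <- predict_sparse(u5, "R99", fit, country = "S2", seed = 2)
  expect_s3_class(p_seen, "q_posterior")
  expect_equal(p_seen$source, "sparse")
  # same container fields as the spline model output
  w <- small_world()
  b3_post <- q_posterior("C01", 2000:2005,
                         matrix(log(0.01), 50, 6), source = "b3")
  expect_identical(names(p_seen), names(b3_post))
  expect_silent(summarize_posterior(p_seen))
  s_seen <- summarize_posterior(p_seen)
  s_unseen <- summarize_posterior(p_unseen)
  expect_true(all(log(s_unseen$upper / s_unseen$lower) >
                    log(s_seen$upper / s_seen$lower)))
  expect_error(predict_sparse(data.frame(year = 2000, u5mr = -1), "R1", fit),
               "positive")
  # deterministic under seed
  expect_identical(predict_sparse(u5, "R1", fit, seed = 9)$draws,
                   predict_sparse(u5, "R1", fit, seed = 9)$draws)
})

test_that("held-out 90% intervals achieve near-nominal coverage", {
  all_pairs <- sim_mixed_world(4500, seed = 8)   # one world, shared region effects
  fit <- fit_mixed(all_pairs[1:3000, ])
  test_pairs <- all_pairs[3001:4500, ]
  hits <- vapply(seq_len(nrow(test_pairs)), function(i) {
    p <- predict_sparse(data.frame(year = 2000, u5mr = exp(test_pairs$logu5mr[i])),
                        test_pairs$region[i], fit, n_draws = 400,
                        seed = 10 + i)
    s <- summarize_posterior(p)
    exp(test_pairs$logq[i]) >= s$lower && exp(test_pairs$logq[i]) <= s$upper
  }, logical(1))
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(hits), 0.95)
})

test_that("predictions are monotone in u5mr when the total slope is positive", {
  pairs <- sim_mixed_world(2000, seed = 12, sd_slope = 0.02)
  fit <- fit_mixed(pairs)
  u5 <- data.frame(year = 2000:2009, u5mr = seq(0.01, 0.1, length.out = 10))
  p <- predict_sparse(u5, "R1", fit, seed = 3)
  med <- summarize_posterior(p)$median
  total_slope <- fit$fixed["slope"] +
    fit$region_effects$slope[fit$region_effects$region == "R1"]
  if (total_slope > 0) expect_true(all(diff(med) > 0))
})
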