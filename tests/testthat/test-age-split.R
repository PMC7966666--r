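make_post <- function(years = 1990:2019, n_draws = 200, level = 0.02, seed = 1) {
  set.seed(seed)
  q_posterior("A", years,
              matrix(log(level) + rnorm(n_draws * length(years), 0, 0.1),
                     n_draws, length(years)))
}

test_that("ratio observations are built, clipped and weighted as specified", {
  post <- make_post()
  med <- apply(exp(post$draws), 2, median)
  obs5 <- data.frame(ref_time = c(1995.5, 2005.5, 2015.5),
                     q = 0.5 * approx(post$years + 0.5, med,
                                      c(1995.5, 2005.5, 2015.5))$y,
                     se_logq = c(0.05, 0.1, 0.2))
  ro <- ratio_observations(obs5, post)
  expect_equal(ro$logit_r, rep(0, 3), tolerance = 1e-9)   # half the median
  expect_true(all(diff(ro$weight) < 0))                   # weight falls with se
  expect_false(any(ro$clipped))
  obs_hi <- obs5; obs_hi$q <- obs_hi$q * 10
  expect_true(all(ratio_observations(obs_hi, post)$clipped))
})

test_that("the ratio spline is exact on constants and linear in the heavy-penalty limit", {
  years <- 1990:2019
  t_obs <- seq(1991, 2018, length.out = 10)
  const <- data.frame(t = t_obs, logit_r = qlogis(0.45), weight = 1)
  f <- fit_ratio_spline(const, years)
  expect_equal(f$r_hat, rep(0.45, length(years)), tolerance = 1e-6)
  # penalty -> infinity: best weighted line in logit space
  set.seed(4)
  drift <- data.frame(t = t_obs, logit_r = -0.2 - 0.01 * (t_obs - 2000) +
                        rnorm(10, 0, 0.03), weight = 1)
  f_inf <- fit_ratio_spline(drift, years, penalty = 1e9)
  line <- lm(logit_r ~ t, data = drift)
  pred <- predict(line, newdata = data.frame(t = years + 0.5))
  expect_equal(qlogis(f_inf$r_hat), unname(pred), tolerance = 1e-3)
  # <= 2 observations: constant fallback at the weighted mean
  two <- data.frame(t = c(2000, 2010), logit_r = qlogis(c(0.4, 0.5)),
                    weight = c(1, 3))
  f2 <- fit_ratio_spline(two, years)
  expect_equal(unique(f2$r_hat),
               plogis(weighted.mean(two$logit_r, two$weight)))
  expect_equal(f2$n_obs_used, 2L)
})

test_that("a drifting ratio is recovered within 0.02 RMSE", {
  years <- 1990:2019
  r_true <- seq(0.45, 0.40, length.out = length(years))
  set.seed(11)
  t_obs <- seq(1991, 2018.5, length.out = 14)
  r_at <- approx(years, r_true, t_obs)$y
  robs <- data.frame(t = t_obs, logit_r = qlogis(r_at) + rnorm(14, 0, 0.05),
                     weight = 100)
  f <- fit_ratio_spline(robs, years)
  expect_lt(sqrt(mean((f$r_hat - r_true)^2)), 0.02)
  expect_true(all(f$r_hat > 0 & f$r_hat < 1))
})

test_that("the split closed form holds and composes back exactly", {
  post <- make_post(level = 0.02, seed = 3)
  f <- structure(list(years = post$years,
                      r_hat = rep(0.5, length(post$years)),
                      smoothing_penalty = Inf, n_obs_used = 0L),
                 class = "ratio_fit")
  # r = 0.5, q = 0.02 -> 5q15 = 0.01, 5q20 = 0.01/0.99
  one <- q_posterior("A", 2000L, matrix(log(0.02), 1, 1))
  sp1 <- apply_split(one, structure(list(years = 2000L, r_hat = 0.5,
                                         smoothing_penalty = Inf, n_obs_used = 0L),
                                    class = "ratio_fit"))
  expect_equal(drop(sp1$q15_19), 0.01, tolerance = 1e-12)
  expect_equal(drop(sp1$q20_24), 0.01 / 0.99, tolerance = 1e-12)
  # composition identity per draw and year
  sp <- apply_split(post, f)
  expect_equal(1 - (1 - sp$q15_19) * (1 - sp$q20_24), exp(post$draws),
               tolerance = 1e-12)
  # r -> 0: the older band carries the whole probability
  f0 <- structure(list(years = post$years,
                       r_hat = rep(1e-9, length(post$years)),
                       smoothing_penalty = Inf, n_obs_used = 0L),
                  class = "ratio_fit")
  sp0 <- apply_split(post, f0)
  expect_equal(sp0$q20_24, exp(post$draws), tolerance = 1e-6)
})
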