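test_that("truth generation is deterministic and respects degenerate settings", {
  t1 <- generate_truth(6, 2, seed = 5)
  t2 <- generate_truth(6, 2, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, generate_truth(6, 2, seed = 6)))
  # zero deviation SD and no year noise -> exactly log-linear paths
  p <- world_params(deviation_sd = 0, link_year_sd = 0)
  tl <- generate_truth(4, 2, seed = 3, params = p)
  for (cc in unique(tl$country)) {
    lq <- log(tl$q15_24_true[tl$country == cc])
    expect_lt(max(abs(residuals(lm(lq ~ seq_along(lq))))), 1e-10)
  }
  expect_true(all(t1$q15_24_true > 0 & t1$q15_24_true < 0.5))
  expect_true(all(t1$ratio_true > 0.2 & t1$ratio_true < 0.8))
})

test_that("generated 2019 world median sits in the configured central range", {
  tr <- generate_truth(200, 4, seed = 11)
  med <- median(1000 * tr$q15_24_true[tr$year == 2019])
  # frozen regression band around the generator's calibrated level
  expect_gt(med, 5); expect_lt(med, 25)
})

test_that("VR simulation is consistent and completeness scales observations", {
  w <- small_world()
  tr <- w$truth[w$truth$country == "C01", ]
  # complete registration, large population: obs within 3 SE of truth
  obs <- simulate_vr(tr, w$population, completeness = 1, seed = 8)
  z <- (log(obs$q) - log(tr$q15_24_true[match(floor(obs$ref_time), tr$year)])) / obs$se_logq
  expect_lt(mean(abs(z) <= 3), 1.01); expect_gt(mean(abs(z) <= 3), 0.95)
  # completeness 0.6: mean observed/true ratio ~ 0.6 over replicates
  ratios <- vapply(1:300, function(s) {
    o <- simulate_vr(tr, w$population, completeness = 0.6, seed = s, years = 2000)
    o$q / tr$q15_24_true[tr$year == 2000]
  }, numeric(1))
  expect_equal(mean(ratios), 0.6, tolerance = 0.02)
  # zero population -> empty series
  pop0 <- w$population; pop0$person_years <- 0
  expect_equal(nrow(simulate_vr(tr, pop0, seed = 1)), 0)
})

test_that("sibling surveys carry the configured recall-bias signature", {
  w <- small_world()
  tr <- w$truth[w$truth$country == "C02", ]
  # zero bias, huge effective n: observations approach the truth
  b0p <- bias_params(sibling_level_bias_sd = 0, sibling_slope_mean = 0,
                     sibling_slope_sd = 0,
                     nonsampling_sd_by_source = c(sibling = 0, census = 0,
                                                  vr_complete = 0,
                                                  vr_incomplete = 0, srs = 0))
  s <- simulate_sibling_survey(tr, 2014.5, b0p, effective_n = 1e7, seed = 2)
  s15 <- s[s$age_start == 15, ]
  truth_at <- exp(approx(tr$year + 0.5, log(tr$q15_24_true), s15$ref_time)$y)
  expect_equal(log(s15$q), log(truth_at), tolerance = 0.02)
  # slope -0.02/yr: mean log bias at lag 10 ~ -0.2 over replicate surveys
  bp <- bias_params(sibling_level_bias_sd = 0, sibling_slope_mean = -0.02,
                    sibling_slope_sd = 0,
                    nonsampling_sd_by_source = c(sibling = 0, census = 0,
                                                 vr_complete = 0,
                                                 vr_incomplete = 0, srs = 0))
  biases <- vapply(1:1000, function(i) {
    ss <- simulate_sibling_survey(tr, 2014.5, bp, effective_n = 1e6, seed = 100 + i)
    row <- ss$age_start == 15 & abs((ss$collection_time - ss$ref_time) - 7.5) < 1e-9
    truth_mid <- exp(approx(tr$year + 0.5, log(tr$q15_24_true), ss$ref_time[row])$y)
    log(ss$q[row]) - log(truth_mid)
  }, numeric(1))
  expect_equal(mean(biases) * (10 / 7.5), -0.2, tolerance = 0.02)
  # reproducible under a fixed seed
  expect_identical(simulate_sibling_survey(tr, 2014.5, seed = 4)$q,
                   simulate_sibling_survey(tr, 2014.5, seed = 4)$q)
  expect_warning(simulate_sibling_survey(tr, 1991.5, seed = 1), "truncated")
})

test_that("census underreporting thins the observed death rate", {
  w <- small_world()
  tr <- w$truth[w$truth$country == "C03", ]
  m_ratio <- vapply(1:300, function(s) {
    full <- simulate_census(tr, w$population, 2010, 1, seed = s)
    half <- simulate_census(tr, w$population, 2010, 0.5, seed = s)
    q_to_m(half$q[half$age_start == 15], 10) /
      q_to_m(full$q[full$age_start == 15], 10)
  }, numeric(1))
  expect_equal(mean(m_ratio), 0.5, tolerance = 0.03)
  expect_identical(simulate_census(tr, w$population, 2010, 0.9, seed = 6),
                   simulate_census(tr, w$population, 2010, 0.9, seed = 6))
})

test_that("crisis overlay composes excess mortality and refuses reapplication", {
  w <- simulate_world(5, 2, seed = 9, with_crises = FALSE)
  truth <- w$truth
  py <- sum(w$population$person_years[w$population$country == "C02" &
                                        w$population$year == 2005 &
                                        w$population$age_start %in% c(15, 20)])
  ev <- data.frame(country = "C02", year = 2005, age_start = 15L,
                   age_width = 10L, excess_deaths = 0.01 * py)
  out <- apply_crisis(truth, ev, w$population)
  q0 <- truth$q15_24_true[truth$country == "C02" & truth$year == 2005]
  q_exc <- m_to_q(0.01, 10)
  expect_equal(out$q15_24_true[out$country == "C02" & out$year == 2005],
               1 - (1 - q0) * (1 - q_exc), tolerance = 1e-12)
  expect_true(out$crisis[out$country == "C02" & out$year == 2005])
  # zero excess leaves the trajectory unchanged
  ev0 <- ev; ev0$excess_deaths <- 0
  expect_equal(apply_crisis(truth, ev0, w$population)$q15_24_true,
               truth$q15_24_true)
  # reapplication is an error
  expect_error(apply_crisis(out, ev, w$population), "reapplication")
  ev_big <- ev; ev_big$excess_deaths <- 0.5 * py
  expect_error(apply_crisis(truth, ev_big, w$population), "0.2")
})

test_that("the assembled world is pure in (params, seed) and schema-valid", {
  w1 <- simulate_world(5, 2, seed = 13)
  w2 <- simulate_world(5, 2, seed = 13)
  expect_identical(w1$observations, w2$observations)
  expect_identical(w1$truth, w2$truth)
  expect_silent(validate_observations(w1$observations))
  expect_setequal(unique(w1$observations$country), unique(w1$truth$country))
})
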