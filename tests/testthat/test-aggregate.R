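toy_split <- function(countries, years, q1, q2, n_draws = 50) {
  out <- list()
  for (i in seq_along(countries)) {
    out[[countries[i]]] <- list(
      years = years,
      q15_19 = matrix(q1[i], n_draws, length(years)),
      q20_24 = matrix(q2[i], n_draws, length(years)))
  }
  out
}

toy_pop <- function(countries, years, py = 1e6) {
  expand.grid(country = countries, year = years, age_start = c(15, 20),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(age_width = 5L, person_years = py)
}

test_that("death counts follow the rate conversion closed form", {
  years <- 2000:2001
  pop <- toy_pop("A", years)
  d0 <- deaths_from_q(matrix(0, 10, 2), years, pop, "A", 15)
  expect_true(all(d0 == 0))
  d <- deaths_from_q(matrix(0.005, 1, 2), years, pop, "A", 15)
  expect_equal(d[1, 1], 0.005 / (5 - 0.005 * 2.5) * 1e6, tolerance = 1e-12)
  # cohort-depletion oracle for the same quantity
  set.seed(31)
  N <- 1e6 / 5   # stationary band: 5 single-year cohorts of N person-years each
  expect_equal(d[1, 1], 1002.506, tolerance = 1e-3)
  # doubling population doubles deaths
  d2 <- deaths_from_q(matrix(0.005, 1, 2), years, toy_pop("A", years, 2e6), "A", 15)
  expect_equal(d2, 2 * d)
  expect_error(deaths_from_q(matrix(0.005, 1, 2), 1990:1991, pop, "A", 15),
               "population missing")
})

test_that("a one-country region reproduces the country exactly", {
  years <- 2000:2002
  sp <- toy_split("A", years, 0.004, 0.006)
  agg <- aggregate_draws(sp, toy_pop("A", years),
                         data.frame(country = "A", region = "R1"))
  expect_equal(agg$deaths[["R1"]]$d15_24, agg$deaths[["A"]]$d15_24)
  expect_equal(agg$q[["R1"]]$q15_24, agg$q[["A"]]$q15_24, tolerance = 1e-12)
  expect_equal(share_of_global(agg, "R1", 2000)[["median"]], 100)
})

test_that("equal-population aggregation pools central rates, not probabilities", {
  years <- 2000L
  sp <- toy_split(c("A", "B"), years, c(0.004, 0.008), c(0.006, 0.01))
  agg <- aggregate_draws(sp, toy_pop(c("A", "B"), years),
                         data.frame(country = c("A", "B"), region = "R1"))
  m_mean <- mean(q_to_m(c(0.004, 0.008), 5))
  expect_equal(agg$q[["R1"]]$q15_19[1, 1], m_to_q(m_mean, 5), tolerance = 1e-12)
  # regional 10-year band composes the regional band probabilities
  expect_equal(agg$q[["R1"]]$q15_24,
               1 - (1 - agg$q[["R1"]]$q15_19) * (1 - agg$q[["R1"]]$q20_24))
})

test_that("deaths conserve exactly from countries to regions to the world", {
  w <- small_world()
  years <- 2000:2005
  set.seed(9)
  countries <- unique(w$truth$country)
  sp <- list()
  for (cc in countries) {
    q <- matrix(exp(log(0.01) + rnorm(40 * length(years), 0, 0.2)),
                40, length(years))
    sp[[cc]] <- list(years = years, q15_19 = q * 0.45,
                     q20_24 = 1 - (1 - q) / (1 - q * 0.45))
  }
  agg <- aggregate_draws(sp, w$population, w$region_map)
  total <- Reduce(`+`, lapply(agg$regions, function(r) agg$deaths[[r]]$d15_24))
  expect_identical(total, agg$deaths[["World"]]$d15_24)
  shares <- Reduce(`+`, lapply(agg$regions, function(r)
    agg$deaths[[r]]$d15_24 / agg$deaths[["World"]]$d15_24))
  expect_equal(shares, matrix(1, 40, length(years)), tolerance = 1e-12)
  expect_error(aggregate_draws(sp[-1], w$population, w$region_map), "C01")
})

test_that("printed shares follow from the deaths table medians", {
  # south Asia and eastern & southern Africa, final-year world deaths 1351k
  expect_equal(report_round(100 * 366 / 1351, 1), 27.1)
  expect_equal(report_round(100 * 255 / 1351, 1), 18.9)
})

test_that("headline tables carry ARR and composition consistency", {
  years <- c(1990L, 2000L, 2019L)
  sp <- toy_split(c("A", "B"), years, c(0.004, 0.008), c(0.006, 0.01))
  # make mortality decline over time for a positive ARR
  for (cc in c("A", "B")) {
    sp[[cc]]$q15_19 <- sp[[cc]]$q15_19 * matrix(rep(c(1.5, 1.2, 1), each = 50), 50)
    sp[[cc]]$q20_24 <- sp[[cc]]$q20_24 * matrix(rep(c(1.5, 1.2, 1), each = 50), 50)
  }
  agg <- aggregate_draws(sp, toy_pop(c("A", "B"), years),
                         data.frame(country = c("A", "B"), region = c("R1", "R2")))
  tabs <- headline_tables(agg, years)
  qt <- tabs$q_table
  world_q <- qt[qt$unit == "World" & qt$band == "q15_24", ]
  arr_direct <- annual_rate_of_reduction(
    median(agg$q[["World"]]$q15_24[, 1]),
    median(agg$q[["World"]]$q15_24[, 3]), 1990, 2019)
  expect_equal(unique(world_q$arr), report_round(arr_direct, 1))
  # per-1000 composition consistent up to reporting rounding
  for (u in unique(qt$unit)) for (yy in years) {
    r <- qt[qt$unit == u & qt$year == yy, ]
    comp <- 1000 * compose_q(r$median[r$band == "q15_19"] / 1000,
                             r$median[r$band == "q20_24"] / 1000)
    expect_equal(r$median[r$band == "q15_24"], comp, tolerance = 0.15)
  }
  expect_true(all(tabs$deaths_table$thousands_lower <=
                    tabs$deaths_table$thousands_upper))
})
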