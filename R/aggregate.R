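#' Deaths, regional aggregation and headline tables
#'
#' Band probabilities become death counts through the central death rate
#' times person-years; draws are summed across countries (so regional and
#' global deaths conserve exactly per draw), regional band probabilities
#' are recovered from pooled rates, and the printed-table quantities --
#' per-1000 probabilities with 90% UIs, annual rates of reduction, death
#' counts in thousands and shares of the global total -- are assembled from
#' the draw summaries.  Population counts carry no uncertainty.
#'
#' @name aggregate_report
NULL

#' Convert band q draws into death-count draws
#'
#' Per draw: `deaths = q_to_m(q) * person_years` for each year.
#'
#' @param q_draws Matrix (draws by years) of band q, per 1.
#' @param years Years matching the columns.
#' @param pop Population table; rows for `country` and `age_start`.
#' @param country Country whose population to use.
#' @param age_start Band start age (15 or 20), width 5.
#' @return Matrix (draws by years) of annual deaths.
#' @export
deaths_from_q <- function(q_draws, years, pop, country, age_start) {
  sel <- pop$country == country & pop$age_start == age_start
  py <- pop$person_years[sel][match(years, pop$year[sel])]
  if (anyNA(py)) {
    stop(sprintf("population missing for %s band %d in some of years %s-%s",
                 country, age_start, min(years), max(years)))
  }
  m <- q_to_m(q_draws, 5)
  sweep(m, 2, py, `*`)
}

#' Aggregate country draws to regions and the world
#'
#' @param split_draws Named list (by country) of [apply_split()] outputs
#'   (draw matrices of 5q15 and 5q20 on a common year grid).
#' @param pop Population table.
#' @param region_map Data frame `country`, `region`; every mapped country
#'   must appear in `split_draws`.
#' @return List of class `deaths_aggregate`: `years`; `deaths` -- named
#'   list by unit (each country, each region, `World`) of lists with draw
#'   matrices `d15_19`, `d20_24`, `d15_24`; `q` -- same units, draw
#'   matrices `q15_19`, `q20_24`, `q15_24` (regional band q from pooled
#'   central rates, composed for the 10-year band); `person_years` by unit.
#' @export
aggregate_draws <- function(split_draws, pop, region_map) {
  miss <- setdiff(region_map$country, names(split_draws))
  if (length(miss)) {
    stop("no draws for mapped countries: ", paste(miss, collapse = ", "))
  }
  countries <- region_map$country
  years <- split_draws[[countries[1]]]$years
  py_of <- function(cc, age) {
    sel <- pop$country == cc & pop$age_start == age
    pop$person_years[sel][match(years, pop$year[sel])]
  }
  deaths <- list(); qs <- list(); pys <- list()
  for (cc in countries) {
    sp <- split_draws[[cc]]
    if (!identical(sp$years, years)) stop("all countries must share the year grid")
    d1 <- deaths_from_q(sp$q15_19, years, pop, cc, 15)
    d2 <- deaths_from_q(sp$q20_24, years, pop, cc, 20)
    deaths[[cc]] <- list(d15_19 = d1, d20_24 = d2, d15_24 = d1 + d2)
    qs[[cc]] <- list(q15_19 = sp$q15_19, q20_24 = sp$q20_24,
                     q15_24 = 1 - (1 - sp$q15_19) * (1 - sp$q20_24))
    pys[[cc]] <- rbind(py15 = py_of(cc, 15), py20 = py_of(cc, 20))
  }
  units <- split(region_map$country, region_map$region)
  for (u in names(units)) {
    member <- units[[u]]
    d1 <- Reduce(`+`, lapply(member, function(k) deaths[[k]]$d15_19))
    d2 <- Reduce(`+`, lapply(member, function(k) deaths[[k]]$d20_24))
    py <- Reduce(`+`, lapply(member, function(k) pys[[k]]))
    q1 <- m_to_q(sweep(d1, 2, py["py15", ], `/`), 5)
    q2 <- m_to_q(sweep(d2, 2, py["py20", ], `/`), 5)
    deaths[[u]] <- list(d15_19 = d1, d20_24 = d2, d15_24 = d1 + d2)
    qs[[u]] <- list(q15_19 = q1, q20_24 = q2,
                    q15_24 = 1 - (1 - q1) * (1 - q2))
    pys[[u]] <- py
  }
  # the world is the sum of its regions, so conservation is exact per draw
  wd <- lapply(c("d15_19", "d20_24", "d15_24"), function(b)
    Reduce(`+`, lapply(names(units), function(r) deaths[[r]][[b]])))
  names(wd) <- c("d15_19", "d20_24", "d15_24")
  py_w <- Reduce(`+`, lapply(names(units), function(r) pys[[r]]))
  q1_w <- m_to_q(sweep(wd$d15_19, 2, py_w["py15", ], `/`), 5)
  q2_w <- m_to_q(sweep(wd$d20_24, 2, py_w["py20", ], `/`), 5)
  deaths[["World"]] <- wd
  qs[["World"]] <- list(q15_19 = q1_w, q20_24 = q2_w,
                        q15_24 = 1 - (1 - q1_w) * (1 - q2_w))
  pys[["World"]] <- py_w
  structure(list(years = years, deaths = deaths, q = qs,
                 person_years = pys, regions = names(units),
                 countries = countries),
            class = "deaths_aggregate")
}

#' Share of global deaths with uncertainty
#'
#' Per draw, the unit's deaths as a percentage of world deaths in the same
#' draw; reported as median and 90% UI.
#'
#' @param agg A `deaths_aggregate`.
#' @param unit Unit name (country, region).
#' @param year Calendar year.
#' @return Named vector `median`, `lower`, `upper` in percent.
#' @export
share_of_global <- function(agg, unit, year) {
  j <- match(year, agg$years)
  if (is.na(j)) stop("year outside the aggregate grid")
  ratio <- 100 * agg$deaths[[unit]]$d15_24[, j] / agg$deaths[["World"]]$d15_24[, j]
  stats::setNames(stats::quantile(ratio, c(0.5, 0.05, 0.95), names = FALSE),
                  c("median", "lower", "upper"))
}

draw_summary <- function(x) {
  stats::setNames(stats::quantile(x, c(0.5, 0.05, 0.95), names = FALSE),
                  c("median", "lower", "upper"))
}

#' Headline probability and deaths tables
#'
#' Builds the two printed-table layouts from an aggregate: per-1000 band
#' probabilities with 90% UIs and the ARR between the first and last
#' report year (point estimate from the medians, interval from the
#' per-draw ARR distribution), and deaths in thousands with shares of the
#' global total and relative changes.
#'
#' @param agg A `deaths_aggregate`.
#' @param years Report years (default `c(1990, 2000, 2019)`).
#' @param decimals Rounding for the probability table (default 1).
#' @return List with data frames `q_table` (unit, band, year, median,
#'   lower, upper per 1000, plus `arr`, `arr_lower`, `arr_upper` on the
#'   10-year band) and `deaths_table` (unit, band, year, thousands, plus
#'   `share_2019`-style share and relative-change columns for the final
#'   year).
#' @export
headline_tables <- function(agg, years = c(1990, 2000, 2019), decimals = 1) {
  years <- intersect(years, agg$years)
  if (length(years) < 2) stop("need at least two report years inside the grid")
  y0 <- years[1]; y1 <- years[length(years)]
  units <- c(agg$regions, "World")
  q_rows <- list(); d_rows <- list()
  for (u in units) {
    arr_draws <- annual_rate_of_reduction(
      agg$q[[u]]$q15_24[, match(y0, agg$years)],
      agg$q[[u]]$q15_24[, match(y1, agg$years)], y0, y1)
    med_q <- function(band, yy) draw_summary(agg$q[[u]][[band]][, match(yy, agg$years)])
    arr_point <- annual_rate_of_reduction(
      stats::median(agg$q[[u]]$q15_24[, match(y0, agg$years)]),
      stats::median(agg$q[[u]]$q15_24[, match(y1, agg$years)]), y0, y1)
    for (band in c("q15_19", "q20_24", "q15_24")) {
      for (yy in years) {
        s <- med_q(band, yy)
        q_rows[[length(q_rows) + 1]] <- data.frame(
          unit = u, band = band, year = yy,
          median = report_round(1000 * s["median"], decimals),
          lower = report_round(1000 * s["lower"], decimals),
          upper = report_round(1000 * s["upper"], decimals),
          arr = if (band == "q15_24") report_round(arr_point, decimals) else NA_real_,
          arr_lower = if (band == "q15_24")
            report_round(stats::quantile(arr_draws, 0.05, names = FALSE), decimals) else NA_real_,
          arr_upper = if (band == "q15_24")
            report_round(stats::quantile(arr_draws, 0.95, names = FALSE), decimals) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    rel_draws <- 100 * (agg$deaths[[u]]$d15_24[, match(y1, agg$years)] /
                          agg$deaths[[u]]$d15_24[, match(y0, agg$years)] - 1)
    for (band in c("d15_19", "d20_24", "d15_24")) {
      for (yy in years) {
        s <- draw_summary(agg$deaths[[u]][[band]][, match(yy, agg$years)]) / 1000
        sh <- if (band == "d15_24") share_of_global(agg, u, y1) else
          c(median = NA_real_, lower = NA_real_, upper = NA_real_)
        d_rows[[length(d_rows) + 1]] <- data.frame(
          unit = u, band = band, year = yy,
          thousands = report_round(s["median"], 0),
          thousands_lower = report_round(s["lower"], 0),
          thousands_upper = report_round(s["upper"], 0),
          share_final = report_round(sh[["median"]], decimals),
          rel_change = if (band == "d15_24" && yy == y1)
            report_round(stats::median(rel_draws), decimals) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  q_table <- do.call(rbind, q_rows); rownames(q_table) <- NULL
  deaths_table <- do.call(rbind, d_rows); rownames(deaths_table) <- NULL
  list(q_table = q_table, deaths_table = deaths_table)
}
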