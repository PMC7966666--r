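#' Abridged life-table identities for age-band death probabilities
#'
#' Core arithmetic shared by every pipeline stage: composing and splitting
#' death probabilities over adjacent age bands, converting between a band
#' probability nqx and the central death rate nmx, and the annual rate of
#' reduction (ARR) summary.  All probabilities are stored per 1; per-1000
#' presentation happens only in the reporting layer.
#'
#' @name lifetable
NULL

#' Compose death probabilities over two adjacent age bands
#'
#' For adjacent bands \eqn{[x, x+n)} and \eqn{[x+n, x+m)}, survival
#' multiplies: the probability of dying over the union is
#' \eqn{1 - (1-q_a)(1-q_b)}.  This is the identity linking 5q15, 5q20
#' and 10q15.
#'
#' @param q_a Death probability over the first band, per 1, in `[0, 1)`.
#' @param q_b Death probability over the adjacent band, per 1, in `[0, 1)`.
#' @return The death probability over the combined band, per 1.
#' @examples
#' compose_q(0.008, 0.0092)   # 5q15 and 5q20 -> 10q15
#' @export
compose_q <- function(q_a, q_b) {
  check_q(q_a, "q_a")
  check_q(q_b, "q_b")
  1 - (1 - q_a) * (1 - q_b)
}

#' Split a composed death probability by removing its leading segment
#'
#' Inverse of [compose_q()]: given the probability over \eqn{[x, x+m)} and
#' over the leading sub-band \eqn{[x, x+n)}, returns the conditional
#' probability over \eqn{[x+n, x+m)}, i.e. \eqn{1 - (1-q_{tot})/(1-q_1)}.
#' Used to derive 5q20 from 10q15 and 5q15.
#'
#' @param q_total Probability over the full band, per 1.
#' @param q_first Probability over the leading sub-band; must not exceed
#'   `q_total`.
#' @return Probability over the trailing band, per 1.
#' @export
split_q <- function(q_total, q_first) {
  check_q(q_total, "q_total")
  check_q(q_first, "q_first")
  if (any(q_first > q_total)) {
    stop("q_first exceeds q_total: the leading segment cannot be deadlier than the whole band")
  }
  1 - (1 - q_total) / (1 - q_first)
}

#' Convert a band death probability to a central death rate
#'
#' Standard abridged life-table conversion
#' \eqn{m = q / (n - q (n - a))}, where `n` is the band width in years and
#' `a` is the average number of years lived within the band by those dying
#' in it (the separation factor).  The default `a_sep = n/2` assumes deaths
#' uniformly distributed within the band, adequate for the near-linear
#' survivorship of the youth bands.
#'
#' @param q Death probability over the band, per 1, in `[0, 1)`.
#' @param n Band width in years (> 0, finite).
#' @param a_sep Average years lived in the band by decedents, in `(0, n)`.
#' @return Central death rate in deaths per person-year.
#' @seealso [m_to_q()] for the exact inverse.
#' @export
q_to_m <- function(q, n, a_sep = n / 2) {
  check_q(q, "q")
  if (any(!is.finite(n) | n <= 0)) stop("band width n must be finite and positive")
  if (any(a_sep <= 0 | a_sep >= n)) stop("a_sep must lie strictly inside (0, n)")
  q / (n - q * (n - a_sep))
}

#' Convert a central death rate to a band death probability
#'
#' Exact inverse of [q_to_m()]: \eqn{q = n m / (1 + (n - a) m)}.
#'
#' @param m Central death rate, deaths per person-year, `>= 0`.
#' @inheritParams q_to_m
#' @return Death probability over the band, per 1.
#' @export
m_to_q <- function(m, n, a_sep = n / 2) {
  if (any(m < 0)) stop("central rate m must be non-negative")
  if (any(!is.finite(n) | n <= 0)) stop("band width n must be finite and positive")
  if (any(a_sep <= 0 | a_sep >= n)) stop("a_sep must lie strictly inside (0, n)")
  n * m / (1 + (n - a_sep) * m)
}

#' Annual rate of reduction between two death probabilities
#'
#' \eqn{ARR = 100 \log(q_1/q_2) / (t_2 - t_1)} in percent per year,
#' positive when mortality declines.
#'
#' @param q1,q2 Death probabilities (per 1 or per 1000, any common scale),
#'   strictly positive.
#' @param t1,t2 Years bracketing the period, `t2 > t1`.
#' @return Annual rate of reduction in percent per year.
#' @export
annual_rate_of_reduction <- function(q1, q2, t1, t2) {
  if (any(q1 <= 0) || any(q2 <= 0)) stop("ARR requires strictly positive probabilities")
  if (any(t2 <= t1)) stop("t2 must exceed t1")
  100 * log(q1 / q2) / (t2 - t1)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Reporting convention for printed tables (base R `round()` rounds half to
#' even, which does not reproduce table arithmetic such as -0.55 -> -0.6).
#'
#' @param x Numeric vector.
#' @param decimals Number of decimal places (default 1).
#' @return `x` rounded half-away-from-zero.
#' @export
report_round <- function(x, decimals = 1) {
  p <- 10^decimals
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_q <- function(q, name) {
  if (any(!is.finite(q)) || any(q < 0) || any(q >= 1)) {
    stop(sprintf("%s must be a probability in [0, 1)", name))
  }
  invisible(q)
}

#' Validate an observation table against the package schema
#'
#' An observation table holds one row per mortality measurement with columns
#' `country`, `series_id`, `source_type` (one of `vr_complete`,
#' `vr_incomplete`, `srs`, `sibling`, `census`), `ref_time` (decimal year at
#' the midpoint of the observation window), `collection_time` (field date;
#' equal to `ref_time` for vital registration), `age_start`, `age_width`,
#' `q` (per 1), `se_logq` (sampling standard error of log q), `excluded`
#' (logical) and `exclusion_reason`.
#'
#' @param obs A data frame of observations.
#' @return `obs`, invisibly, with `excluded`/`exclusion_reason` added when
#'   absent.  Stops with an informative error on schema violations.
#' @export
validate_observations <- function(obs) {
  required <- c("country", "series_id", "source_type", "ref_time",
                "collection_time", "age_start", "age_width", "q", "se_logq")
  missing <- setdiff(required, names(obs))
  if (length(missing)) {
    stop("observation table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"excluded" %in% names(obs)) obs$excluded <- FALSE
  if (!"exclusion_reason" %in% names(obs)) obs$exclusion_reason <- NA_character_
  bad_type <- setdiff(unique(obs$source_type), source_types())
  if (length(bad_type)) {
    stop("unknown source_type: ", paste(bad_type, collapse = ", "))
  }
  if (any(!is.finite(obs$q) | obs$q < 0 | obs$q >= 1)) {
    stop("observation q values must lie in [0, 1) (store per 1, not per 1000)")
  }
  lag <- obs$collection_time - obs$ref_time
  if (any(lag < -1e-9)) stop("collection_time must not precede ref_time")
  retro <- obs$source_type %in% c("sibling", "census")
  if (any(retro & !(obs$se_logq > 0))) {
    stop("sibling and census observations require a positive se_logq")
  }
  if (any(obs$age_width <= 0) || any(obs$age_start < 0)) {
    stop("age bands must have age_start >= 0 and age_width > 0")
  }
  invisible(obs)
}

source_types <- function() {
  c("vr_complete", "vr_incomplete", "srs", "sibling", "census")
}

#' Retrospective lag of each observation
#'
#' Years between a survey or census field date and the period the
#' observation refers to; zero for vital registration.
#'
#' @param obs Observation table (see [validate_observations()]).
#' @return Numeric vector of lags in years.
#' @export
obs_lag <- function(obs) {
  pmax(obs$collection_time - obs$ref_time, 0)
}
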