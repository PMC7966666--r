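#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of (params, seed).
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("a single integer seed is required")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic child seeds below 2^31, spread by a fixed multiplier
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7907 * k) %% 2147483647)
}

# linear interpolation of a per-year series at decimal times
interp_series <- function(years, values, t) {
  stats::approx(years, values, xout = t, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
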