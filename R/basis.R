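#' Cubic B-spline basis on equally spaced knots
#'
#' Builds the temporal basis used for the latent log 10q15 trend and for the
#' age-split ratio model: degree-3 B-splines on knots spaced `knot_spacing`
#' years apart, extended past both ends of the domain so that every year up
#' to the projection year is strictly inside the span and the basis forms a
#' partition of unity there.  Shrinking second-order differences of the
#' coefficients towards zero shrinks the fitted trend towards a straight
#' line in log q.
#'
#' @param year_min,year_max First and last calendar year the basis must
#'   cover (include the projection year in `year_max`).
#' @param knot_spacing Distance between interior knots in years (default 2.5).
#' @param degree Spline degree (default 3, cubic).
#' @return An object of class `spline_basis`: list with `knots` (full,
#'   extended knot vector), `interior` (boundary-to-boundary knots),
#'   `degree`, `n_basis`, `domain` and `greville` (Greville abscissae, the
#'   coefficient "sites" at which a linear trend in t maps exactly onto
#'   linear coefficients).
#' @export
build_basis <- function(year_min, year_max, knot_spacing = 2.5, degree = 3) {
  if (year_max <= year_min) stop("year_max must exceed year_min")
  n_int <- ceiling((year_max - year_min) / knot_spacing - 1e-9)
  if (n_int < 3) stop("basis domain must span at least 3 knot intervals")
  interior <- year_min + knot_spacing * (0:n_int)
  knots <- c(year_min - knot_spacing * (degree:1), interior,
             interior[length(interior)] + knot_spacing * (1:degree))
  n_basis <- n_int + degree
  grev <- vapply(seq_len(n_basis), function(k) {
    mean(knots[(k + 1):(k + degree)])
  }, numeric(1))
  structure(
    list(knots = knots, interior = interior, degree = degree,
         n_basis = n_basis, domain = c(year_min, interior[length(interior)]),
         greville = grev),
    class = "spline_basis"
  )
}

#' Evaluate a spline basis at a set of times
#'
#' @param basis A `spline_basis` from [build_basis()].
#' @param t Times (decimal years) inside the basis domain.
#' @return Matrix `length(t)` by `basis$n_basis` of basis function values.
#' @export
eval_basis <- function(basis, t) {
  stopifnot(inherits(basis, "spline_basis"))
  if (any(t < basis$domain[1] - 1e-9) || any(t > basis$domain[2] + 1e-9)) {
    stop(sprintf("evaluation times must lie in the basis domain [%s, %s]",
                 basis$domain[1], basis$domain[2]))
  }
  t <- pmin(pmax(t, basis$domain[1]), basis$domain[2] - 1e-9)
  splines::splineDesign(basis$knots, t, ord = basis$degree + 1)
}

#' Second-order difference matrix for a coefficient vector
#'
#' @param k Number of coefficients.
#' @return A `(k-2)` by `k` matrix `D` with rows `(1, -2, 1)`.
#' @keywords internal
diff2_matrix <- function(k) {
  diff(diag(k), differences = 2)
}
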