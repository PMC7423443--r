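#' One-parameter point transformation of the (tau, y) plane
#'
#' Two families are provided, each forming a representation of a
#' one-parameter Lie group (composition adds parameters, epsilon = 0 is the
#' identity):
#'
#' * `"translation"`: (tau, y) -> (tau + epsilon, y). Because the
#'   dimensionless Hill rate has no explicit time dependence, this is a
#'   symmetry of every model order.
#' * `"hill"` of order n: (tau, y) ->
#'   (-y e^eps + (tau + y) e^{-(n-1) eps}, y e^eps). This is a symmetry of
#'   the order-n Hill model and of no other order, which is what makes it
#'   usable for model selection.
#'
#' @param family `"translation"` or `"hill"`.
#' @param epsilon group parameter (finite real).
#' @param order model order n; required for the hill family.
#' @return An object of class `point_transform`.
#' @examples
#' point_transform("hill", epsilon = log(2), order = 2)
#' @export
point_transform <- function(family = c("translation", "hill"), epsilon, order = NULL) {
  family <- match.arg(family)
  if (!is_number(epsilon)) stop_f("`epsilon` must be a single finite number")
  if (family == "hill") {
    if (is.null(order) || !is_number(order) || order < 1) {
      stop_f("the hill family requires `order` >= 1")
    }
  } else {
    order <- NULL
  }
  structure(list(family = family, epsilon = epsilon, order = order),
            class = "point_transform")
}

#' @export
print.point_transform <- function(x, ...) {
  cat(sprintf("Point transform: %s%s, epsilon = %g\n", x$family,
              if (is.null(x$order)) "" else sprintf(" (order %g)", x$order),
              x$epsilon))
  invisible(x)
}

#' Apply a point transformation
#'
#' Maps points (tau, y) to their images under the transform; vectorized
#' over points. The transformed concentration is always >= 0 for y >= 0.
#'
#' @param transform a [point_transform()].
#' @param tau time coordinate(s).
#' @param y concentration coordinate(s), >= 0.
#' @return A list with components `tau` and `y` (the transformed points).
#' @examples
#' apply_point(point_transform("hill", log(2), order = 2), tau = 0, y = 1)
#' @export
apply_point <- function(transform, tau, y) {
  stopifnot(inherits(transform, "point_transform"))
  if (length(tau) != length(y)) stop_f("`tau` and `y` must share a length")
  if (any(y < 0)) stop_f("`y` must be >= 0")
  eps <- transform$epsilon
  if (transform$family == "translation") {
    list(tau = tau + eps, y = y)
  } else {
    n <- transform$order
    yh <- y * exp(eps)
    list(tau = -yh + (tau + y) * exp(-(n - 1) * eps), y = yh)
  }
}

#' Invert a point transformation
#'
#' The group inverse: same family and order with parameter -epsilon.
#'
#' @param transform a [point_transform()].
#' @return The inverse [point_transform()].
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "point_transform"))
  point_transform(transform$family, -transform$epsilon, transform$order)
}

#' Compose two point transformations
#'
#' The group law: transforms of identical family and order compose to the
#' same family/order with added parameters. Composition across families or
#' orders is not closed and raises an error.
#'
#' @param a,b [point_transform()] objects of identical family and order.
#' @return The composition as a [point_transform()].
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "point_transform"), inherits(b, "point_transform"))
  if (a$family != b$family || !identical(a$order, b$order)) {
    stop_f("cannot compose transforms of different family or order")
  }
  point_transform(a$family, a$epsilon + b$epsilon, a$order)
}

#' Transform a dimensionless series
#'
#' Applies the transform to every (tau_i, y_i) point and re-sorts the image
#' by transformed time so downstream fitting sees time-ordered data (the
#' hill transform does not guarantee order preservation for arbitrary
#' epsilon). The scaling object is carried through unchanged. If two image
#' points coincide in time within 1e-12 the image is no longer a function
#' of time and a degenerate-transform error is raised.
#'
#' @param transform a [point_transform()].
#' @param dseries a [dimensionless_series()].
#' @return The transformed [dimensionless_series()].
#' @export
transform_series <- function(transform, dseries) {
  stopifnot(inherits(dseries, "dimensionless_series"))
  img <- apply_point(transform, dseries$tau, dseries$y)
  ord <- order(img$tau)
  tau <- img$tau[ord]
  if (any(diff(tau) < 1e-12)) {
    stop_f("degenerate transform (%s, epsilon = %g): transformed times coincide",
           transform$family, transform$epsilon)
  }
  dimensionless_series(tau, img$y[ord], dseries$scaling)
}

#' Numerical symmetry defect
#'
#' Oracle for solution-set closure that involves no optimizer: integrate
#' the order-`model_order` dimensionless ODE from `y0` on a dense grid
#' spanning the decay to 10% of `y0`, apply the requested transform to the
#' trajectory, and return the standard deviation of the order-`model_order`
#' first integral along the transformed points. The first integral is
#' constant along solutions, so the defect is ~0 exactly when the
#' transformed curve is again a solution: for the hill family this happens
#' iff `transform_order == model_order`, for the translation family always.
#'
#' @param transform_order order of the hill transform (ignored for the
#'   translation family).
#' @param model_order order of the model whose solution is transformed.
#' @param epsilon transformation parameter.
#' @param y0 initial dimensionless concentration, > 0.
#' @param family transform family, `"hill"` (default) or `"translation"`.
#' @param n_grid number of trajectory points.
#' @param rtol,atol integration tolerances (tight, so the defect measures
#'   closure rather than integrator error).
#' @return The defect (standard deviation of the first integral), >= 0.
#' @examples
#' symmetry_defect(2, 2, epsilon = 0.5, y0 = 3.65)  # ~0: true symmetry
#' symmetry_defect(3, 2, epsilon = 0.5, y0 = 3.65)  # > 0: not a symmetry
#' @export
symmetry_defect <- function(transform_order, model_order, epsilon, y0,
                            family = c("hill", "translation"),
                            n_grid = 512L, rtol = 1e-12, atol = 1e-14) {
  family <- match.arg(family)
  if (!is_number(y0) || y0 <= 0) stop_f("`y0` must be a single number > 0")
  if (!is_number(epsilon)) stop_f("`epsilon` must be finite")
  tau_end <- hill_g(model_order, y0) - hill_g(model_order, 0.1 * y0)
  grid <- seq(0, tau_end, length.out = n_grid)
  y <- solve_dimensionless(model_order, y0, grid, rtol = rtol, atol = atol)
  tr <- point_transform(family, epsilon,
                        order = if (family == "hill") transform_order else NULL)
  img <- apply_point(tr, grid, y)
  if (any(img$y <= 0)) stop_f("transformed trajectory left the domain y > 0")
  stats::sd(first_integral(model_order, img$tau, img$y))
}
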