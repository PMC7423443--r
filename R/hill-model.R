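#' Hill kinetic model
#'
#' Parameterization of the Hill rate law dS/dt = -v_max S^n / (K_m + S^n)
#' for enzymatic substrate depletion. `n` is the Hill coefficient (order),
#' `v_max` the maximum reaction rate in mM/min and `K_m` the substrate
#' concentration (mM) at half-maximal rate. Integer orders are the standard
#' use; any real `n >= 1` is accepted.
#'
#' @param n model order (Hill coefficient), >= 1.
#' @param v_max maximum reaction rate, mM/min, > 0.
#' @param K_m half-maximal substrate concentration, mM, > 0.
#' @return An object of class `hill_model`.
#' @examples
#' hill_model(2, v_max = 0.0102, K_m = 0.30)
#' @export
hill_model <- function(n, v_max, K_m) {
  if (!is_number(n) || n < 1) stop_f("`n` must be a single number >= 1, got %s", format(n))
  if (!is_number(v_max) || v_max <= 0) stop_f("`v_max` must be a single positive number")
  if (!is_number(K_m) || K_m <= 0) stop_f("`K_m` must be a single positive number")
  structure(list(n = n, v_max = v_max, K_m = K_m), class = "hill_model")
}

#' @export
print.hill_model <- function(x, ...) {
  cat(sprintf("Hill model (order n = %g): v_max = %g mM/min, K_m = %g mM\n",
              x$n, x$v_max, x$K_m))
  invisible(x)
}

#' Dimensional Hill rate
#'
#' Right-hand side of the dimensional Hill ODE, -v_max S^n / (K_m + S^n).
#' Always <= 0 and equal to 0 only at S = 0 (substrate exhaustion is a
#' fixed point).
#'
#' @param model a [hill_model()].
#' @param S substrate concentration(s), mM, >= 0.
#' @return dS/dt in mM/min (vectorized over `S`).
#' @examples
#' hill_rhs(hill_model(1, 0.0102, 0.30), 0.30)  # -v_max / 2
#' @export
hill_rhs <- function(model, S) {
  stopifnot(inherits(model, "hill_model"))
  if (any(!is.finite(S)) || any(S < 0)) stop_f("`S` must be finite and >= 0")
  w <- S^model$n
  -model$v_max * w / (model$K_m + w)
}

#' Dimensionless Hill rate
#'
#' Right-hand side of the dimensionless Hill ODE, omega_n(y) = -y^n/(1+y^n).
#' Bounded in (-1, 0]; has no explicit time dependence, which is why time
#' translation is a symmetry of every order.
#'
#' @param n model order, >= 1.
#' @param y dimensionless concentration(s), >= 0.
#' @return dy/dtau (vectorized over `y`).
#' @examples
#' hill_rhs_dimensionless(2, 2)  # -4/5
#' @export
hill_rhs_dimensionless <- function(n, y) {
  if (!is_number(n) || n < 1) stop_f("`n` must be a single number >= 1")
  if (any(!is.finite(y)) || any(y < 0)) stop_f("`y` must be finite and >= 0")
  w <- y^n
  out <- -w / (1 + w)
  out[is.infinite(w)] <- -1
  out
}

#' Substrate time series
#'
#' An observed (t, S) series: time in minutes (strictly increasing) and
#' substrate concentration in mM (non-negative).
#'
#' @param t time points, minutes, strictly increasing, length >= 2.
#' @param S substrate concentrations, mM, >= 0, same length as `t`.
#' @param label free-text label.
#' @return An object of class `time_series`.
#' @export
time_series <- function(t, S, label = "") {
  if (!is.numeric(t) || !is.numeric(S)) stop_f("`t` and `S` must be numeric")
  if (length(t) != length(S)) stop_f("`t` and `S` must have the same length")
  if (length(t) < 2) stop_f("a time series needs at least 2 points")
  if (any(!is.finite(t)) || any(!is.finite(S))) stop_f("`t` and `S` must be finite")
  if (any(diff(t) <= 0)) {
    i <- which(diff(t) <= 0)[1] + 1L
    stop_f("`t` must be strictly increasing (violated at point %d)", i)
  }
  if (any(S < 0)) stop_f("`S` must be >= 0 (violated at point %d)", which(S < 0)[1])
  structure(list(t = as.numeric(t), S = as.numeric(S), label = as.character(label)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("Substrate time series%s: %d points, t in [%g, %g] min, S in [%g, %g] mM\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$t), min(x$t), max(x$t), min(x$S), max(x$S)))
  invisible(x)
}

#' Nondimensionalizing scales of a Hill model
#'
#' The scales tau = t / time_scale, y = S / conc_scale with
#' conc_scale = K_m^(1/n) and time_scale = K_m^(1/n) / v_max remove both
#' kinetic parameters from the Hill ODE, leaving dy/dtau = -y^n/(1+y^n).
#' All parameter dependence of the dimensionless picture lives here.
#'
#' @param model a [hill_model()].
#' @return An object of class `hill_scaling` with fields `n`, `time_scale`
#'   (min) and `conc_scale` (mM).
#' @export
hill_scaling <- function(model) {
  stopifnot(inherits(model, "hill_model"))
  cs <- model$K_m^(1 / model$n)
  structure(list(n = model$n, time_scale = cs / model$v_max, conc_scale = cs),
            class = "hill_scaling")
}

#' @export
print.hill_scaling <- function(x, ...) {
  cat(sprintf("Hill scaling (n = %g): time_scale = %g min, conc_scale = %g mM\n",
              x$n, x$time_scale, x$conc_scale))
  invisible(x)
}

#' Dimensionless series
#'
#' A (tau, y) series, the image of a [time_series()] under the scaling of a
#' candidate model. Carries the scaling so it can be mapped back.
#'
#' @param tau dimensionless times, strictly increasing, length >= 2.
#' @param y dimensionless concentrations, >= 0.
#' @param scaling the [hill_scaling()] that produced it.
#' @return An object of class `dimensionless_series`.
#' @export
dimensionless_series <- function(tau, y, scaling) {
  stopifnot(inherits(scaling, "hill_scaling"))
  if (length(tau) != length(y) || length(tau) < 2) {
    stop_f("`tau` and `y` must share a length >= 2")
  }
  if (any(!is.finite(tau)) || any(!is.finite(y))) stop_f("`tau` and `y` must be finite")
  if (any(diff(tau) <= 0)) stop_f("`tau` must be strictly increasing")
  if (any(y < 0)) stop_f("`y` must be >= 0")
  structure(list(tau = as.numeric(tau), y = as.numeric(y), scaling = scaling),
            class = "dimensionless_series")
}

#' Map a time series to dimensionless coordinates
#'
#' @param series a [time_series()].
#' @param scaling a [hill_scaling()].
#' @return A [dimensionless_series()] with tau = t / time_scale,
#'   y = S / conc_scale.
#' @seealso [from_dimensionless()] for the exact inverse.
#' @export
to_dimensionless <- function(series, scaling) {
  stopifnot(inherits(series, "time_series"), inherits(scaling, "hill_scaling"))
  if (scaling$time_scale <= 0 || scaling$conc_scale <= 0) stop_f("scales must be positive")
  dimensionless_series(series$t / scaling$time_scale, series$S / scaling$conc_scale,
                       scaling)
}

#' Map a dimensionless series back to physical units
#'
#' @param dseries a [dimensionless_series()].
#' @param label label for the resulting [time_series()].
#' @return A [time_series()] with t = tau * time_scale, S = y * conc_scale.
#' @export
from_dimensionless <- function(dseries, label = "") {
  stopifnot(inherits(dseries, "dimensionless_series"))
  sc <- dseries$scaling
  time_series(dseries$tau * sc$time_scale, dseries$y * sc$conc_scale, label)
}
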