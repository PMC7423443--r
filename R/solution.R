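# Closed-form solution machinery for the dimensionless Hill ODE
# dy/dtau = -y^n/(1+y^n). Separation of variables gives the strictly
# increasing "solution potential"
#   g_n(y) = y + log y                 (n = 1)
#   g_n(y) = y - y^(1-n)/(n-1)         (n > 1)
# so that every solution satisfies g_n(y) + tau = C for some constant C.
# g_n maps (0, Inf) onto (-Inf, Inf), hence y(tau; C) = g_n^{-1}(C - tau)
# is defined for all real arguments and parameterizes the full solution
# family by the single constant C.

hill_g <- function(n, y) {
  if (n == 1) y + log(y) else y - y^(1 - n) / (n - 1)
}

# derivative g_n'(y) = 1 + y^(-n) > 0
hill_g_prime <- function(n, y) 1 + y^(-n)

# Invert g_n(y) = s for y > 0, vectorized over s. Safeguarded Newton in
# u = log y: F(u) = g_n(e^u) - s is strictly increasing, with analytic
# starting brackets, bisection fallback and machine-precision stopping.
hill_g_inv <- function(n, s) {
  if (any(!is.finite(s))) stop_f("`s` must be finite in hill_g_inv()")
  if (length(s) == 0L) return(numeric(0))
  # bracket: F(lo) < 0 < F(hi)
  hi <- log(pmax(s, 1) + 2)
  lo <- if (n == 1) pmin(s, 0) - 2 else -log((n - 1) * (abs(s) + 2)) / (n - 1)
  Fu <- function(u) {
    y <- exp(u)
    if (n == 1) y + u - s else y - exp((1 - n) * u) / (n - 1) - s
  }
  u <- (lo + hi) / 2
  for (iter in seq_len(200L)) {
    f <- Fu(u)
    hi <- ifelse(f > 0, u, hi)
    lo <- ifelse(f > 0, lo, u)
    y <- exp(u)
    fp <- if (n == 1) y + 1 else y + exp((1 - n) * u)
    step <- f / fp
    unew <- u - step
    # fall back to bisection when Newton leaves the bracket
    bad <- !is.finite(unew) | unew <= lo | unew >= hi
    unew[bad] <- (lo[bad] + hi[bad]) / 2
    done <- abs(f) <= 1e-14 * (1 + abs(s)) | (hi - lo) <= 4e-16 * (1 + abs(u))
    u <- ifelse(done, u, unew)
    if (all(done)) break
  }
  exp(u)
}

#' First integral of the dimensionless Hill ODE
#'
#' The conserved quantity C(n, tau, y) = g_n(y) + tau with
#' g_n(y) = y + log(y) for n = 1 and g_n(y) = y - y^(1-n)/(n-1) for n > 1,
#' obtained by separation of variables. C is constant along every exact
#' solution of dy/dtau = -y^n/(1+y^n), which makes it an optimizer-free
#' oracle for solution-set membership. Defined only for y > 0 (it diverges
#' at y = 0 for n >= 2).
#'
#' @param n model order, >= 1.
#' @param tau dimensionless time(s).
#' @param y dimensionless concentration(s), > 0.
#' @return The constant(s) C (vectorized).
#' @examples
#' first_integral(1, tau = 0, y = 1)  # 1
#' first_integral(3, tau = 2, y = 1)  # 2.5
#' @export
first_integral <- function(n, tau, y) {
  if (!is_number(n) || n < 1) stop_f("`n` must be a single number >= 1")
  if (any(!is.finite(y)) || any(y <= 0)) stop_f("`y` must be finite and > 0")
  if (any(!is.finite(tau))) stop_f("`tau` must be finite")
  hill_g(n, y) + tau
}

#' Evaluate the dimensionless solution family
#'
#' Returns y(tau; C) = g_n^{-1}(C - tau), the exact solution of
#' dy/dtau = -y^n/(1+y^n) with first-integral constant C, at the requested
#' times. Complements the numerical integrator [solve_dimensionless()];
#' the fitting pipeline uses this closed form.
#'
#' @param n model order, >= 1.
#' @param tau dimensionless time(s).
#' @param C first-integral constant.
#' @return y values, > 0 (vectorized over `tau`).
#' @export
hill_solution <- function(n, tau, C) {
  if (!is_number(n) || n < 1) stop_f("`n` must be a single number >= 1")
  if (!is_number(C)) stop_f("`C` must be a single finite number")
  hill_g_inv(n, C - tau)
}

#' Integrate the dimensionless Hill ODE numerically
#'
#' Adaptive integration of dy/dtau = -y^n/(1+y^n) from y(tau_grid[1]) = y0
#' with tight tolerances (the closed-form first integral is used as an
#' accuracy oracle in the test suite, so local error control matters more
#' than speed here). y stays strictly positive for finite tau when y0 > 0;
#' tiny negative excursions within `atol` are clipped to zero, anything
#' larger raises an error because physical solutions satisfy S >= 0.
#'
#' @param n model order, >= 1.
#' @param y0 initial dimensionless concentration, >= 0.
#' @param tau_grid strictly increasing times; the first entry is the
#'   initial time.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return Numeric vector y(tau_grid).
#' @export
solve_dimensionless <- function(n, y0, tau_grid, rtol = 1e-10, atol = 1e-12) {
  if (!is_number(n) || n < 1) stop_f("`n` must be a single number >= 1")
  if (!is_number(y0) || y0 < 0) stop_f("`y0` must be a single number >= 0")
  if (length(tau_grid) < 1 || any(!is.finite(tau_grid)) || any(diff(tau_grid) <= 0)) {
    stop_f("`tau_grid` must be finite and strictly increasing")
  }
  if (y0 == 0) return(rep(0, length(tau_grid)))
  rhs <- function(t, y, parms) list(hill_rhs_dimensionless(n, max(y, 0)))
  out <- deSolve::ode(y = c(y = y0), times = tau_grid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0) {
    stop_f("integration of the dimensionless Hill ODE failed (istate = %d)",
           attr(out, "istate")[1])
  }
  y <- out[, "y"]
  if (any(y < -atol)) stop_f("integrator produced negative concentrations beyond atol")
  pmax(y, 0)
}

#' Integrate the dimensional Hill ODE
#'
#' Solves dS/dt = -v_max S^n / (K_m + S^n) from S(t_grid[1]) = S0 on the
#' requested time grid via the model's nondimensionalization and
#' [solve_dimensionless()].
#'
#' @param model a [hill_model()].
#' @param S0 initial substrate concentration, mM, >= 0.
#' @param t_grid strictly increasing times, minutes.
#' @param rtol,atol integration tolerances (dimensionless units).
#' @return Numeric vector S(t_grid), mM.
#' @export
solve_hill <- function(model, S0, t_grid, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(model, "hill_model"))
  if (!is_number(S0) || S0 < 0) stop_f("`S0` must be a single number >= 0")
  sc <- hill_scaling(model)
  y <- solve_dimensionless(model$n, S0 / sc$conc_scale, t_grid / sc$time_scale,
                           rtol = rtol, atol = atol)
  y * sc$conc_scale
}

# Solve g_n(base + delta) - g_n(base) = q for delta, vectorized over
# (base, q), base > 0, delta in (-base, Inf). The increment form
#   n = 1:  G(delta) = delta + log1p(delta/base)
#   n >= 2: G(delta) = delta + (base^(1-n) - (base+delta)^(1-n))/(n-1)
# avoids the catastrophic cancellation of evaluating g_n at large
# transformed coordinates and subtracting: under the order-n symmetry at
# large (n-1)*epsilon all transformed solutions collapse onto tau = -y and
# their vertical separations shrink like e^{-(n-1) eps}, far below the
# rounding noise of the raw coordinates. This function measures those
# separations exactly. Used by the transformed-space least-squares fit.
hill_g_increment_solve <- function(n, base, q) {
  k <- length(q)
  if (length(base) != k) stop_f("`base` and `q` must share a length")
  G <- function(d) {
    if (n == 1) d + log1p(d / base)
    else d + (base^(1 - n) - (base + d)^(1 - n)) / (n - 1)
  }
  d <- q / hill_g_prime(n, base)          # Newton start from linearization
  # brackets by sign of q (G is strictly increasing, G(0) = 0)
  lo <- ifelse(q >= 0, 0, -base)
  hi <- ifelse(q >= 0, Inf, 0)
  # expand finite upper bound for q > 0
  pos <- q > 0
  if (any(pos)) {
    h <- pmax(d, 1)
    for (i in seq_len(200L)) {
      need <- pos & G(h) < q
      if (!any(need)) break
      h[need] <- h[need] * 2
    }
    hi[pos] <- h[pos]
  }
  # keep the start strictly inside the bracket
  inside <- d > lo & d < hi
  d[!inside] <- ifelse(is.finite(hi[!inside]),
                       (lo[!inside] + hi[!inside]) / 2, lo[!inside] / 2)
  for (iter in seq_len(100L)) {
    f <- G(d) - q
    hi <- ifelse(f > 0, d, hi)
    lo <- ifelse(f > 0, lo, d)
    fp <- hill_g_prime(n, base + d)
    dnew <- d - f / fp
    mid <- ifelse(is.finite(hi), (lo + hi) / 2, lo + 2 * pmax(abs(lo), 1))
    bad <- !is.finite(dnew) | dnew <= lo | dnew >= hi
    dnew[bad] <- mid[bad]
    done <- abs(f) <= 1e-15 * (1 + abs(q)) |
      (is.finite(hi) & (hi - lo) <= 1e-16 * (base + abs(d)))
    d <- ifelse(done, d, dnew)
    if (all(done)) break
  }
  d
}
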