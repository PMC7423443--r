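#' Options controlling the least-squares fit
#'
#' Parameters are optimized in log space (log v_max, log K_m and, when
#' `fit_initial_value` is `TRUE`, log S0) to enforce positivity, from
#' `multistart` starting points: the data-derived nominal guess plus
#' seeded Latin-hypercube draws over the box `bound_factor * nominal`.
#' The best objective wins; ties are broken by the smallest log-parameter
#' norm.
#'
#' @param fit_initial_value should S(0) be a free parameter? (Default
#'   `TRUE`: simulated series observe t = 0 with noise, so S0 is not known
#'   exactly.)
#' @param multistart number of optimizer starts, >= 1.
#' @param bound_factor length-2 positive multipliers of the nominal
#'   parameter scale giving the lower/upper box bounds.
#' @param tol convergence tolerance on the objective.
#' @param max_eval maximum objective evaluations per start.
#' @param seed seed for the Latin-hypercube starts.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(fit_initial_value = TRUE, multistart = 5L,
                        bound_factor = c(1e-4, 1e2), tol = 1e-10,
                        max_eval = 1000L, seed = 1L) {
  stopifnot(is.logical(fit_initial_value), length(bound_factor) == 2)
  if (!is_number(multistart) || multistart < 1) stop_f("`multistart` must be >= 1")
  if (any(bound_factor <= 0) || !all(is.finite(bound_factor)) ||
      bound_factor[1] >= bound_factor[2]) {
    stop_f("`bound_factor` must be finite, positive and increasing")
  }
  if (!is_number(tol) || tol <= 0) stop_f("`tol` must be > 0")
  structure(list(fit_initial_value = fit_initial_value,
                 multistart = as.integer(multistart),
                 bound_factor = bound_factor, tol = tol,
                 max_eval = as.integer(max_eval), seed = as.integer(seed)),
            class = "fit_options")
}

#' Root-mean-square of paired residuals
#'
#' @param observed,predicted numeric vectors of equal length >= 1.
#' @return sqrt(mean((observed - predicted)^2)).
#' @examples
#' rms(c(1, 2), c(0, 0))  # sqrt(5/2)
#' @export
rms <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1) {
    stop_f("`observed` and `predicted` must share a length >= 1")
  }
  sqrt(mean((observed - predicted)^2))
}

# dimensional residuals (mM) of a candidate parameter iterate against a
# series, via the closed-form dimensionless solution family. Residuals are
# dimensional on purpose: a dimensionless objective under the iterate's own
# scaling would reward the optimizer for inflating K_m (all residuals shrink
# by K_m^(-1/n)) independent of fit quality.
hill_fit_residuals <- function(par, t, S, n, fit_s0, S_first) {
  v_max <- exp(par[[1]]); K_m <- exp(par[[2]])
  S0 <- if (fit_s0) exp(par[[3]]) else S_first
  cs <- K_m^(1 / n)
  tau <- v_max * t / cs
  C <- hill_g(n, S0 / cs) + tau[1]
  pred <- tryCatch(cs * hill_g_inv(n, C - tau), error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred))) return(rep(1e6, length(t)))
  S - pred
}

# Least squares over the affine-scaled solution family y = a g^{-1}(C - b tau)
# in the frozen scaling of an incumbent (v0, K0); returns the dimensional
# parameter image of the optimum and its dimensional deviance. Used as an
# alternative-parameterization polish by fit_hill().
affine_polish <- function(t, S, n, v0, K0, S0_0, options) {
  cs0 <- K0^(1 / n)
  tau <- (t - t[1]) * v0 / cs0
  y <- S / cs0
  if (any(y <= 0)) return(NULL)
  m <- length(y)
  resid <- function(theta) {
    la <- theta[[1]]; ut <- theta[[2]]; Cc <- theta[[3]]
    a <- exp(la); b <- 1 / a + ut
    x <- y / a
    q <- if (n == 1) Cc + ut * y - b * (tau + y) - log(y) + la
         else Cc + ut * y - b * (tau + y) + a^(n - 1) * y^(1 - n) / (n - 1)
    if (b <= 0 || any(!is.finite(q))) return(rep(1e6, m))
    d <- tryCatch(hill_g_increment_solve(n, x, q), error = function(e) NULL)
    if (is.null(d) || any(!is.finite(d))) return(rep(1e6, m))
    -a * d
  }
  st <- c(0, 0, hill_g(n, S0_0 / cs0))
  res <- tryCatch(
    minpack.lm::nls.lm(par = st, fn = resid,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-15, ptol = 1e-15, gtol = 0,
                         maxfev = options$max_eval,
                         maxiter = min(options$max_eval, 1024L))),
    error = function(e) NULL)
  if (is.null(res) || !all(is.finite(res$par))) return(NULL)
  a <- exp(res$par[[1]]); b <- 1 / a + res$par[[2]]; Cc <- res$par[[3]]
  if (b <= 0) return(NULL)
  list(v_max = a * b * v0, K_m = (a * cs0)^n,
       S0 = a * cs0 * hill_g_inv(n, Cc),
       deviance = res$deviance * cs0^2)
}

#' Fit a Hill model of fixed order to a time series
#'
#' Classical least squares: minimizes the sum of squared residuals
#' sum (S_i - Shat(t_i))^2 in concentration units over (v_max, K_m,
#' optionally S0), where Shat is the exact Hill solution of order `n_fit`.
#' The reported `rho0` is the residual RMS in mM, a common unit across
#' candidate orders and the same unit in which the symmetry statistic
#' rho(epsilon) is reported, so the two are directly comparable. (A
#' dimensionless objective under the candidate's own iterate scaling is
#' deliberately avoided: it degenerates, because inflating K_m shrinks
#' every rescaled residual regardless of fit quality.)
#'
#' Non-convergence of every start is flagged (`converged = FALSE`) rather
#' than raised, so selection can exclude the candidate gracefully.
#'
#' @param series a [time_series()] with >= 3 points (>= 4 when S0 is
#'   fitted).
#' @param n_fit candidate model order.
#' @param options a [fit_options()].
#' @return An object of class `fit_result` with fields `model` (the fitted
#'   [hill_model()]), `S0_hat`, `rho0`, `converged`, `n_starts_used`.
#' @examples
#' des <- default_design(2, noise = noise_model(0))
#' fit_hill(generate_series(des, 0), n_fit = 2)
#' @export
fit_hill <- function(series, n_fit, options = fit_options()) {
  stopifnot(inherits(series, "time_series"), inherits(options, "fit_options"))
  if (!is_number(n_fit) || n_fit < 1) stop_f("`n_fit` must be a single number >= 1")
  m <- length(series$t)
  need <- if (options$fit_initial_value) 4L else 3L
  if (m < need) stop_f("fitting needs at least %d points, series has %d", need, m)

  t <- series$t - series$t[1]        # fit relative to the first observation
  S <- series$S
  fit_s0 <- options$fit_initial_value
  # nominal parameter scale derived from the data
  v_nom <- max((max(S) - min(S)) / (max(t) - min(t)), .Machine$double.eps)
  K_nom <- max(median(S), .Machine$double.eps)
  S0_nom <- max(S[1], .Machine$double.eps)
  nominal <- log(c(v_nom, K_nom, if (fit_s0) S0_nom))
  lower <- nominal + log(options$bound_factor[1])
  upper <- nominal + log(options$bound_factor[2])
  npar <- length(nominal)

  starts <- matrix(nominal, nrow = 1)
  if (options$multistart > 1) {
    u <- with_seed(options$seed, lhs::randomLHS(options$multistart - 1L, npar))
    starts <- rbind(starts, sweep(u, 2, upper - lower, `*`) +
                              matrix(lower, nrow(u), npar, byrow = TRUE))
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = lower, upper = upper,
        fn = hill_fit_residuals, t = t, S = S, n = n_fit,
        fit_s0 = fit_s0, S_first = S[1],
        control = minpack.lm::nls.lm.control(
          ftol = min(options$tol, 1e-14), ptol = 1e-14, gtol = 0,
          maxfev = options$max_eval, maxiter = min(options$max_eval, 1024L))),
      error = function(e) NULL)
    if (is.null(res)) next
    obj <- res$deviance
    conv <- res$info %in% 1:4
    if (is.null(best) ||
        obj < best$obj * (1 - 1e-12) ||
        (abs(obj - best$obj) <= 1e-12 * max(obj, best$obj) &&
         sum(res$par^2) < sum(best$res$par^2))) {
      best <- list(res = res, obj = obj, conv = conv)
    }
  }

  if (!is.null(best)) {
    # polish restart: a fresh Levenberg-Marquardt run from the incumbent
    # clears the damping state and digs the last ~1e-8 out of flat valleys
    polish <- tryCatch(
      minpack.lm::nls.lm(
        par = best$res$par, lower = lower, upper = upper,
        fn = hill_fit_residuals, t = t, S = S, n = n_fit,
        fit_s0 = fit_s0, S_first = S[1],
        control = minpack.lm::nls.lm.control(
          ftol = 1e-15, ptol = 1e-15, gtol = 0,
          maxfev = options$max_eval, maxiter = min(options$max_eval, 1024L))),
      error = function(e) NULL)
    if (!is.null(polish) && polish$deviance < best$obj) {
      best <- list(res = polish, obj = polish$deviance, conv = best$conv)
    }
    if (fit_s0) {
      # affine-parameterization polish: re-optimizing in (log a, u_t, C)
      # around the incumbent's own scaling walks a different path through
      # parameter space and escapes the occasional sloppy-valley basin the
      # (log v, log K, log S0) runs get stuck in; iterate to a fixed point
      for (round in 1:3) {
        par <- best$res$par
        ap <- affine_polish(t, S, n_fit, exp(par[[1]]), exp(par[[2]]),
                            exp(par[[3]]), options)
        if (is.null(ap) || ap$deviance >= best$obj * (1 - 1e-12)) break
        restart <- tryCatch(
          minpack.lm::nls.lm(
            par = pmin(pmax(log(c(ap$v_max, ap$K_m, ap$S0)), lower), upper),
            lower = lower, upper = upper,
            fn = hill_fit_residuals, t = t, S = S, n = n_fit,
            fit_s0 = fit_s0, S_first = S[1],
            control = minpack.lm::nls.lm.control(
              ftol = 1e-15, ptol = 1e-15, gtol = 0,
              maxfev = options$max_eval,
              maxiter = min(options$max_eval, 1024L))),
          error = function(e) NULL)
        if (is.null(restart) || restart$deviance >= best$obj) break
        best <- list(res = restart, obj = restart$deviance, conv = best$conv)
      }
    }
  }

  if (is.null(best)) {
    return(structure(list(model = hill_model(n_fit, v_nom, K_nom),
                          S0_hat = S0_nom, rho0 = Inf, converged = FALSE,
                          n_starts_used = nrow(starts), series_label = series$label,
                          t_origin = series$t[1]),
                     class = "fit_result"))
  }
  par <- best$res$par
  model <- hill_model(n_fit, exp(par[[1]]), exp(par[[2]]))
  S0_hat <- if (fit_s0) exp(par[[3]]) else S[1]
  structure(list(model = model, S0_hat = S0_hat,
                 rho0 = sqrt(best$obj / m), converged = best$conv,
                 n_starts_used = nrow(starts), series_label = series$label,
                 t_origin = series$t[1]),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("Hill fit (order %g): v_max = %.6g mM/min, K_m = %.6g mM, ",
                     "S0 = %.6g mM\n  rho0 = %.6g mM, converged: %s\n"),
              x$model$n, x$model$v_max, x$model$K_m, x$S0_hat, x$rho0,
              x$converged))
  invisible(x)
}

# serialize a fit result to a plain list (JSON-ready)
fit_result_to_list <- function(fit) {
  list(order = fit$model$n, v_max = fit$model$v_max, K_m = fit$model$K_m,
       S0_hat = fit$S0_hat, rho0 = fit$rho0, converged = fit$converged)
}

#' Classical residual-based model selection
#'
#' Fits every candidate order to every replicate series, summarizes each
#' candidate by the mean of rho0 across replicates with a standard error
#' sd/sqrt(N), and selects the candidate with the smallest mean only if
#' its one-standard-error interval overlaps no other candidate's;
#' otherwise the overlapping candidates are reported as indistinguishable.
#' Candidates whose intervals lie entirely above the best candidate's are
#' rejected. A candidate that fails to converge on any replicate is
#' excluded with a warning recorded in the verdict.
#'
#' @param replicates a [time_series()] or list of them (the N replicate
#'   series).
#' @param candidate_orders at least two distinct candidate orders.
#' @param options a [fit_options()].
#' @return A `selection_verdict` (method `"classical"`); its
#'   `$summary` data frame carries mean and SE of rho0 per candidate.
#' @export
classical_selection <- function(replicates, candidate_orders,
                                options = fit_options()) {
  if (inherits(replicates, "time_series")) replicates <- list(replicates)
  stopifnot(length(replicates) >= 1,
            all(vapply(replicates, inherits, logical(1), "time_series")))
  candidate_orders <- unique(candidate_orders)
  if (length(candidate_orders) < 2) stop_f("need at least 2 candidate orders")

  n_rep <- length(replicates)
  rho0 <- matrix(NA_real_, length(candidate_orders), n_rep)
  warnings <- character(0)
  excluded <- numeric(0)
  for (ci in seq_along(candidate_orders)) {
    for (ri in seq_len(n_rep)) {
      fit <- fit_hill(replicates[[ri]], candidate_orders[ci], options)
      if (!fit$converged || !is.finite(fit$rho0)) {
        excluded <- c(excluded, candidate_orders[ci])
        warnings <- c(warnings, sprintf(
          "candidate order %g failed to converge on replicate %d; excluded",
          candidate_orders[ci], ri))
        break
      }
      rho0[ci, ri] <- fit$rho0
    }
  }
  excluded <- unique(excluded)
  keep <- !candidate_orders %in% excluded
  mean_rho <- rowMeans(rho0)
  se_rho <- if (n_rep > 1) apply(rho0, 1, sd) / sqrt(n_rep) else rep(0, nrow(rho0))
  summary <- data.frame(order = candidate_orders, mean_rho0 = mean_rho,
                        se_rho0 = se_rho, excluded = !keep)

  if (sum(keep) < 2) {
    return(selection_verdict("classical", selected_order = NA_real_,
                             rejected_orders = numeric(0),
                             indistinguishable_orders = candidate_orders[keep],
                             excluded_orders = excluded, summary = summary,
                             diagnostics = c(warnings,
                               "fewer than 2 candidates converged")))
  }
  ords <- candidate_orders[keep]
  mu <- mean_rho[keep]; se <- se_rho[keep]
  best <- which.min(mu)
  overlaps <- which(vapply(seq_along(ords), function(j) {
    j != best && (mu[best] + se[best]) >= (mu[j] - se[j])
  }, logical(1)))
  if (length(overlaps) == 0) {
    sel <- ords[best]
    indist <- numeric(0)
    rej <- ords[-best]
  } else {
    sel <- NA_real_
    indist <- sort(c(ords[best], ords[overlaps]))
    rej <- sort(setdiff(ords, indist))
  }
  selection_verdict("classical", selected_order = sel, rejected_orders = rej,
                    indistinguishable_orders = indist, excluded_orders = excluded,
                    summary = summary, diagnostics = warnings)
}
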