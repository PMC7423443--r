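# selection_verdict: shared container for classical and symmetry verdicts.
selection_verdict <- function(method, selected_order, rejected_orders,
                              indistinguishable_orders, excluded_orders = numeric(0),
                              summary = NULL, eps_range_used = NULL,
                              steady_state_reached = NULL, diagnostics = character(0)) {
  sets <- list(if (!is.na(selected_order)) selected_order else numeric(0),
               rejected_orders, indistinguishable_orders)
  all_orders <- sort(unlist(sets))
  if (anyDuplicated(all_orders)) {
    stop_f("internal error: verdict sets must be disjoint")
  }
  structure(list(method = method, selected_order = selected_order,
                 rejected_orders = rejected_orders,
                 indistinguishable_orders = indistinguishable_orders,
                 excluded_orders = excluded_orders, summary = summary,
                 eps_range_used = eps_range_used,
                 steady_state_reached = steady_state_reached,
                 diagnostics = diagnostics),
            class = "selection_verdict")
}

#' @export
print.selection_verdict <- function(x, ...) {
  cat(sprintf("%s model selection verdict\n",
              if (x$method == "classical") "Classical (rho0)" else "Symmetry-based"))
  cat(sprintf("  selected order:          %s\n",
              if (is.na(x$selected_order)) "none" else format(x$selected_order)))
  cat(sprintf("  rejected orders:         %s\n",
              if (length(x$rejected_orders)) paste(x$rejected_orders, collapse = ", ") else "-"))
  cat(sprintf("  indistinguishable:       %s\n",
              if (length(x$indistinguishable_orders)) paste(x$indistinguishable_orders, collapse = ", ") else "-"))
  if (length(x$excluded_orders)) {
    cat(sprintf("  excluded (no fit):       %s\n", paste(x$excluded_orders, collapse = ", ")))
  }
  if (!is.null(x$eps_range_used)) {
    cat(sprintf("  epsilon range used:      [%g, %g]\n",
                x$eps_range_used[1], x$eps_range_used[2]))
  }
  for (d in x$diagnostics) cat("  note: ", d, "\n", sep = "")
  invisible(x)
}

#' Transform-fit-invert residual at one epsilon
#'
#' The symmetry statistic rho(epsilon) for one candidate on one series:
#'
#' 1. the data are nondimensionalized with the candidate's reference-fit
#'    scaling (the classical fit at epsilon = 0);
#' 2. the transform (of the requested family, hill order = the candidate
#'    order) is applied to the data points;
#' 3. the candidate model is refitted to the transformed data by least
#'    squares over its kinetic parameters -- in the fixed dimensionless
#'    coordinates this is the affine-scaled solution family
#'    y = a g_n^{-1}(C - b tau), the image of varying (v_max, K_m, S0)
#'    under the frozen scaling;
#' 4. the fitted curve is evaluated densely, pulled back through the
#'    inverse transform, interpolated at the original times with a
#'    shape-preserving monotone cubic, and its residual RMS against the
#'    original series is returned in concentration units (mM), the same
#'    unit as rho0.
#'
#' The refit of the full kinetic parameter set in step 3 is what gives the
#' statistic its power. The candidate's one-constant dimensionless family
#' is closed under its own symmetry (indeed under time translation -- for
#' an autonomous first-order ODE the family *is* the translation orbit),
#' so a refit of the constant alone would always pull back into the
#' family and rho(epsilon) would stay flat for every candidate. The
#' rescaling directions (a, b) are not closed under the transform: when
#' the candidate order is the true one the refit reproduces a = b = 1
#' (exactly for noiseless data, since the transformed data remain an
#' exact solution) and the pullback undoes the transform, while a wrong
#' candidate absorbs part of the epsilon-distortion into a drift of its
#' kinetic parameters, its pullback leaves the solution family, and the
#' residual on the original series grows.
#'
#' Numerically the transverse parameters are fitted in pullback scale and
#' the residuals evaluated through a cancellation-free increment
#' formulation, so the statistic stays well-conditioned at large
#' (n-1)*epsilon, where all transformed order-n solutions collapse onto
#' the line tau = -y with vertical spacings of order e^{-(n-1) eps} and
#' naive arithmetic in the raw coordinates (~e^eps) would lose them to
#' rounding.
#'
#' rho(0) reproduces the classical rho0 to optimizer tolerance. An inner
#' fit failure yields `NA` (flagged, not an error); a transform that makes
#' the series non-functional in time raises a degenerate-transform error
#' naming the offending epsilon.
#'
#' @param series the original [time_series()].
#' @param n_candidate candidate model order.
#' @param family `"hill"` or `"translation"`.
#' @param epsilon transformation parameter.
#' @param ref_fit the candidate's classical [fit_hill()] result on this
#'   series (defines the forward scaling and the refit starting point).
#' @param options a [fit_options()] (tolerances).
#' @param warm_start optional parameter vector (log v_max, log K_m, C_pullback)
#'   from a neighbouring epsilon, used as an extra refit start.
#' @return rho(epsilon) >= 0 (mM), or `NA` if the inner fit failed. The
#'   refit parameter vector is attached as attribute `"par"` for
#'   warm-starting.
#' @export
rho_at_eps <- function(series, n_candidate, family = c("hill", "translation"),
                       epsilon, ref_fit, options = fit_options(),
                       warm_start = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(series, "time_series"), inherits(ref_fit, "fit_result"))
  if (!is_number(epsilon)) stop_f("`epsilon` must be a single finite number")
  if (ref_fit$model$n != n_candidate) {
    stop_f("`ref_fit` is for order %g, not candidate order %g",
           ref_fit$model$n, n_candidate)
  }
  n <- n_candidate
  sc0 <- hill_scaling(ref_fit$model)
  t_rel <- series$t - series$t[1]
  tau <- t_rel / sc0$time_scale
  y <- series$S / sc0$conc_scale
  if (any(y <= 0)) stop_f("symmetry fitting requires strictly positive concentrations")

  # contract check: the transformed series must remain a function of time
  transform_series(point_transform(family, epsilon,
                                   order = if (family == "hill") n else NULL),
                   dimensionless_series(tau, y, sc0))

  hill_fam <- family == "hill"
  ee <- exp(epsilon)
  s_eps <- if (hill_fam && n > 1) exp(-(n - 1) * epsilon) else 1
  m <- length(y)

  # Transformed-space least squares over the candidate's full dimensional
  # solution family, y = a * g_n^{-1}(C - b*tau), expressed in the frozen
  # reference coordinates. theta = (log a, u_t, Cc) where the transverse
  # stretch parameters are carried in pullback scale:
  #   b  = 1/a + u_t * e^{-n eps},   C = s_eps * Cc            (hill n >= 2)
  #   b  = 1/a + u_t * e^{-eps},     C = Cc + eps              (hill n = 1)
  #   b  = u_t,                      C = Cc + b*eps            (translation)
  # With this parameterization every ingredient of the residual is O(1)
  # arithmetic times a common factor, so the fit resolves the transverse
  # structure of the transformed data even at large (n-1)*eps where raw
  # transformed coordinates (~e^eps) would drown it in rounding noise.
  refit_residuals <- function(theta) {
    la <- theta[[1]]; ut <- theta[[2]]; Cc <- theta[[3]]
    a <- exp(la)
    if (hill_fam) {
      b <- 1 / a + ut * exp(-n * epsilon)
      x <- y * ee / a
      q <- if (n == 1) {
        Cc + ut * y - b * (tau + y) - log(y) + la
      } else {
        s_eps * (Cc + ut * y - b * (tau + y) + a^(n - 1) * y^(1 - n) / (n - 1))
      }
    } else {
      b <- ut
      x <- y / a
      q <- Cc - b * tau - hill_g(n, x)
    }
    if (b <= 0 || any(!is.finite(q)) || any(!is.finite(x)) || any(x <= 0)) {
      return(rep(1e6, m))
    }
    d <- tryCatch(hill_g_increment_solve(n, x, q), error = function(e) NULL)
    if (is.null(d) || any(!is.finite(d))) return(rep(1e6, m))
    -a * d
  }

  C0 <- hill_g(n, ref_fit$S0_hat / sc0$conc_scale)
  start0 <- c(0, if (hill_fam) 0 else 1, C0)
  starts <- list(start0)
  # the translation objective is epsilon-free, so the refit is run from the
  # canonical start only: every epsilon then performs bit-identical
  # arithmetic and Delta(eps) vanishes exactly rather than to optimizer noise
  if (hill_fam && !is.null(warm_start)) starts <- c(starts, list(warm_start))

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = refit_residuals,
                         control = minpack.lm::nls.lm.control(
                           ftol = min(options$tol, 1e-14), ptol = 1e-14,
                           gtol = 0, maxfev = options$max_eval,
                           maxiter = min(options$max_eval, 1024L))),
      error = function(e) NULL)
    if (!is.null(res) && all(is.finite(res$par)) &&
        (is.null(best) || res$deviance < best$deviance)) {
      best <- res
    }
  }
  if (is.null(best)) {
    warning(sprintf("inner refit failed for order %g, %s family at epsilon = %g",
                    n, family, epsilon))
    return(NA_real_)
  }
  # never leave with something worse than the canonical start (the
  # reference fit's own parameters, which are exact at epsilon = 0)
  dev0 <- sum(refit_residuals(start0)^2)
  if (is.finite(dev0) && dev0 < best$deviance) {
    best <- list(par = start0, deviance = dev0)
  }

  # Step 4: pull the fitted curve back through the inverse transform. In
  # pullback parameterization the inverse image has the explicit stable
  # form tau_p(y_p) below (for a = 1, u_t = 0, b = 1 it reduces to the
  # candidate's own solution with constant Cc); it is sampled densely,
  # sorted, and interpolated at the original times with a shape-preserving
  # monotone cubic.
  la <- best$par[[1]]; ut <- best$par[[2]]; Cc <- best$par[[3]]
  a <- exp(la)
  pullback_tau <- function(yp) {
    if (hill_fam) {
      b <- 1 / a + ut * exp(-n * epsilon)
      if (n == 1) {
        -yp + (Cc + la + ut * yp - log(yp)) / b
      } else {
        -yp + (Cc + ut * yp + a^(n - 1) * yp^(1 - n) / (n - 1)) / b
      }
    } else {
      (Cc - hill_g(n, yp / a)) / ut
    }
  }
  out <- tryCatch({
    lo <- min(y) / 3; hi <- max(y) * 3
    for (k in seq_len(8L)) {
      yg <- exp(seq(log(lo), log(hi), length.out = 512L))
      tp <- pullback_tau(yg)
      keep <- is.finite(tp)
      yg <- yg[keep]; tp <- tp[keep]
      if (length(tp) > 16 && min(tp) <= min(tau) && max(tp) >= max(tau)) break
      lo <- lo / 4; hi <- hi * 4
    }
    if (min(tp) > min(tau) || max(tp) < max(tau)) {
      stop("pullback curve does not cover the data window")
    }
    # the dense samples bracket each original time; the exact inverse image
    # is then resolved on the closed-form curve by bisection, which avoids
    # any interpolation error in rho
    ord <- order(tp)
    tp <- tp[ord]; yg <- yg[ord]
    j <- findInterval(tau, tp, all.inside = TRUE)
    y_a <- yg[j]; y_b <- yg[j + 1L]
    for (it in seq_len(100L)) {
      y_mid <- (y_a + y_b) / 2
      f_mid <- pullback_tau(y_mid) - tau
      below <- f_mid <= 0
      y_a <- ifelse(below, y_mid, y_a)
      y_b <- ifelse(below, y_b, y_mid)
      if (max(abs(y_b - y_a)) <= 1e-15 * max(abs(y_b))) break
    }
    sc0$conc_scale * rms(y, (y_a + y_b) / 2)
  }, error = function(e) NA_real_)
  if (is.na(out)) {
    warning(sprintf("pullback failed for order %g, %s family at epsilon = %g",
                    n, family, epsilon))
    return(NA_real_)
  }
  attr(out, "par") <- best$par
  out
}

#' rho(epsilon) along a parameter grid
#'
#' Maps [rho_at_eps()] over an increasing epsilon grid starting at 0, with
#' the reference fit computed once (at epsilon = 0) and reused. Inner-fit
#' failures appear as `NA` entries and are reported, never silently
#' dropped.
#'
#' @param series a [time_series()].
#' @param n_candidate candidate model order.
#' @param family `"hill"` or `"translation"`.
#' @param eps_grid increasing grid starting at 0.
#' @param options a [fit_options()].
#' @param ref_fit optional precomputed reference fit (computed if `NULL`).
#' @param replicate_index bookkeeping tag.
#' @return An object of class `rho_curve` with fields `candidate_order`,
#'   `family`, `eps_grid`, `rho`, `rho0`, `ref_fit`, `replicate_index`.
#' @export
rho_curve <- function(series, n_candidate, family = c("hill", "translation"),
                      eps_grid, options = fit_options(), ref_fit = NULL,
                      replicate_index = NA_integer_) {
  family <- match.arg(family)
  if (length(eps_grid) < 1 || eps_grid[1] != 0 ||
      (length(eps_grid) > 1 && any(diff(eps_grid) <= 0))) {
    stop_f("`eps_grid` must increase from 0")
  }
  ref_fit <- ref_fit %||% fit_hill(series, n_candidate, options)
  rho <- numeric(length(eps_grid))
  warm <- NULL
  for (j in seq_along(eps_grid)) {
    r <- rho_at_eps(series, n_candidate, family, eps_grid[j], ref_fit, options,
                    warm_start = warm)
    rho[j] <- as.numeric(r)
    if (!is.na(rho[j])) warm <- attr(r, "par")
  }
  structure(list(candidate_order = n_candidate, family = family,
                 eps_grid = eps_grid, rho = rho, rho0 = ref_fit$rho0,
                 ref_fit = ref_fit, replicate_index = replicate_index),
            class = "rho_curve")
}

#' @export
print.rho_curve <- function(x, ...) {
  cat(sprintf("rho(eps) curve: order %g, %s family, %d points on [%g, %g], rho0 = %.4g\n",
              x$candidate_order, x$family, length(x$eps_grid),
              min(x$eps_grid), max(x$eps_grid), x$rho0))
  invisible(x)
}

#' Aggregate replicate rho curves into a confidence band
#'
#' Pointwise mean and standard error (sd/sqrt(N)) over replicates sharing
#' candidate, family and grid. Non-finite entries are excluded pointwise
#' with the effective N recorded; with a single replicate the SE is zero.
#'
#' @param curves list of [rho_curve()] objects.
#' @return An object of class `banded_curve` with fields `candidate_order`,
#'   `family`, `eps_grid`, `mean_rho`, `se_rho`, `n_eff`, `n_replicates`,
#'   `rho0_mean`.
#' @export
aggregate_replicates <- function(curves) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "rho_curve")))
  ref <- curves[[1]]
  for (cv in curves[-1]) {
    if (cv$candidate_order != ref$candidate_order || cv$family != ref$family ||
        length(cv$eps_grid) != length(ref$eps_grid) ||
        any(cv$eps_grid != ref$eps_grid)) {
      stop_f("curves must share candidate order, family and epsilon grid")
    }
  }
  mat <- do.call(rbind, lapply(curves, `[[`, "rho"))
  n_eff <- colSums(is.finite(mat))
  mean_rho <- apply(mat, 2, function(v) mean(v[is.finite(v)]))
  se_rho <- vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[is.finite(mat[, j]), j]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  }, numeric(1))
  structure(list(candidate_order = ref$candidate_order, family = ref$family,
                 eps_grid = ref$eps_grid, mean_rho = mean_rho, se_rho = se_rho,
                 n_eff = n_eff, n_replicates = length(curves),
                 rho0_mean = mean(vapply(curves, `[[`, numeric(1), "rho0"))),
            class = "banded_curve")
}

#' Relative residual curve Delta(epsilon)
#'
#' Delta(eps) = rho(eps)/rho0 - 1; zero means the transformation has no
#' effect on the quality of fit, the expected outcome when the transform
#' is a true symmetry of the fitted model. The default reference is the
#' curve's own rho(0) -- which reproduces the classical rho0 to solver
#' tolerance -- so that Delta(0) = 0 holds exactly rather than up to
#' optimizer noise (the distinction only matters when rho0 is itself at
#' the numerical noise floor, e.g. for noiseless self-fits).
#'
#' @param curve a [rho_curve()].
#' @param rho0 the reference residual, > 0 (defaults to the curve's
#'   rho(0)).
#' @return An object of class `delta_curve` with fields `candidate_order`,
#'   `family`, `eps_grid`, `delta`.
#' @export
delta_curve <- function(curve, rho0 = curve$rho[1]) {
  stopifnot(inherits(curve, "rho_curve"))
  if (!is_number(rho0) || rho0 <= 0) {
    stop_f("`rho0` must be > 0 (a perfect noiseless self-fit has no relative scale)")
  }
  structure(list(candidate_order = curve$candidate_order, family = curve$family,
                 eps_grid = curve$eps_grid, delta = curve$rho / rho0 - 1),
            class = "delta_curve")
}

#' Has a banded rho curve reached a steady state?
#'
#' TRUE iff over the trailing window (the last `window_fraction` of the
#' grid) the relative change of the mean curve, |max - min| / max, is
#' below `rel_tol`. Used to decide whether the epsilon range is long
#' enough for selection.
#'
#' @param band a [aggregate_replicates()] band (>= 5 grid points).
#' @param window_fraction trailing fraction of the grid, in (0, 1].
#' @param rel_tol relative-change tolerance, > 0.
#' @return Logical.
#' @export
steady_state_reached <- function(band, window_fraction = 0.2, rel_tol = 0.01) {
  stopifnot(inherits(band, "banded_curve"))
  L <- length(band$eps_grid)
  if (L < 5) stop_f("steady-state detection needs at least 5 grid points")
  idx <- seq.int(max(1L, L - ceiling(window_fraction * L) + 1L), L)
  v <- band$mean_rho[idx]
  v <- v[is.finite(v)]
  if (length(v) < 2) return(FALSE)
  if (max(v) == 0) return(TRUE)
  (max(v) - min(v)) / max(v) < rel_tol
}

# trailing-window indices shared by steady state and separation rules
trailing_window <- function(L, window_fraction) {
  seq.int(max(1L, L - ceiling(window_fraction * L) + 1L), L)
}

#' Symmetry-based model selection from replicate bands
#'
#' Over the trailing window of the epsilon grid, candidate A counts as
#' separated below candidate B when mean_A + SE_A < mean_B - SE_B at every
#' window point (pointwise non-overlap of the one-standard-error bands).
#' The candidate separated below all others is selected; candidates
#' separated above it are rejected; candidates whose bands overlap the
#' best one are indistinguishable from it and no selection is made.
#' Steady-state status is recorded per candidate.
#'
#' @param bands list of [aggregate_replicates()] bands on a shared grid,
#'   >= 2 candidates.
#' @param window_fraction trailing fraction of the grid used for the
#'   comparison.
#' @return A `selection_verdict` (method `"symmetry"`).
#' @export
symmetry_selection <- function(bands, window_fraction = 0.2) {
  stopifnot(length(bands) >= 2,
            all(vapply(bands, inherits, logical(1), "banded_curve")))
  grid <- bands[[1]]$eps_grid
  for (b in bands[-1]) {
    if (length(b$eps_grid) != length(grid) || any(b$eps_grid != grid)) {
      stop_f("bands must share the epsilon grid")
    }
  }
  orders <- vapply(bands, `[[`, numeric(1), "candidate_order")
  idx <- trailing_window(length(grid), window_fraction)
  lo <- lapply(bands, function(b) (b$mean_rho - b$se_rho)[idx])
  hi <- lapply(bands, function(b) (b$mean_rho + b$se_rho)[idx])
  sep_below <- function(a, b) all(is.finite(hi[[a]]) & is.finite(lo[[b]]) &
                                    hi[[a]] < lo[[b]])
  steady <- setNames(vapply(bands, steady_state_reached, logical(1),
                            window_fraction = window_fraction), orders)
  mean_w <- vapply(bands, function(b) {
    v <- b$mean_rho[idx]
    if (any(is.finite(v))) mean(v[is.finite(v)]) else Inf
  }, numeric(1))
  # a candidate whose rho could not be evaluated anywhere in the comparison
  # window (its own transform destroys its fit) is rejected outright and
  # reported, never silently dropped
  broken <- !is.finite(mean_w)
  diagnostics <- character(0)
  if (any(broken)) {
    diagnostics <- sprintf(
      "order %g: no finite rho(eps) in the comparison window; rejected",
      orders[broken])
    if (sum(!broken) < 2) {
      return(selection_verdict("symmetry", selected_order = NA_real_,
                               rejected_orders = sort(orders[broken]),
                               indistinguishable_orders = sort(orders[!broken]),
                               eps_range_used = range(grid),
                               steady_state_reached = steady,
                               summary = band_summary(bands, idx),
                               diagnostics = diagnostics))
    }
  }
  best <- which.min(mean_w)
  others <- setdiff(which(!broken), best)
  separated <- vapply(others, function(j) sep_below(best, j), logical(1))
  if (all(separated)) {
    verdict <- selection_verdict("symmetry", selected_order = orders[best],
                                 rejected_orders = sort(c(orders[others],
                                                          orders[broken])),
                                 indistinguishable_orders = numeric(0),
                                 eps_range_used = range(grid),
                                 steady_state_reached = steady,
                                 summary = band_summary(bands, idx),
                                 diagnostics = diagnostics)
  } else {
    indist <- sort(c(orders[best], orders[others[!separated]]))
    rej <- sort(c(orders[others[separated]], orders[broken]))
    verdict <- selection_verdict("symmetry", selected_order = NA_real_,
                                 rejected_orders = rej,
                                 indistinguishable_orders = indist,
                                 eps_range_used = range(grid),
                                 steady_state_reached = steady,
                                 summary = band_summary(bands, idx),
                                 diagnostics = c(diagnostics, sprintf(
                                   "bands of orders {%s} overlap over the trailing window",
                                   paste(indist, collapse = ", "))))
  }
  verdict
}

band_summary <- function(bands, idx) {
  data.frame(
    order = vapply(bands, `[[`, numeric(1), "candidate_order"),
    window_mean_rho = vapply(bands, function(b) mean(b$mean_rho[idx]), numeric(1)),
    window_mean_se = vapply(bands, function(b) mean(b$se_rho[idx]), numeric(1)),
    steady_state = vapply(bands, steady_state_reached, logical(1)))
}

#' Run the full symmetry-based selection pipeline
#'
#' Fits every candidate classically to every replicate (the reference
#' fits), computes hill-family rho(epsilon) curves on a uniform grid,
#' aggregates them into one-SE bands and applies [symmetry_selection()].
#' With `extend = TRUE` the epsilon range is doubled until every
#' candidate's band has reached a steady state or `eps_cap` is hit,
#' mirroring the protocol of extending the transformation range until the
#' residual curves flatten.
#'
#' @param replicates a [time_series()] or list of them.
#' @param candidate_orders at least two distinct candidate orders.
#' @param family `"hill"` (selection) or `"translation"` (validation).
#' @param eps_max upper end of the epsilon grid.
#' @param eps_points number of uniform grid points (>= 5).
#' @param options a [fit_options()].
#' @param extend double the range until steady state or `eps_cap`?
#' @param eps_cap hard cap on the extended range.
#' @param window_fraction trailing window for separation/steady state.
#' @return A list of class `symmetry_selection_result`: `verdict`, `bands`,
#'   `curves` (per candidate x replicate), `ref_fits`, `eps_max_used`.
#' @export
run_symmetry_selection <- function(replicates, candidate_orders,
                                   family = c("hill", "translation"),
                                   eps_max = 10, eps_points = 50L,
                                   options = fit_options(), extend = FALSE,
                                   eps_cap = 30, window_fraction = 0.2) {
  family <- match.arg(family)
  if (inherits(replicates, "time_series")) replicates <- list(replicates)
  candidate_orders <- unique(candidate_orders)
  if (length(candidate_orders) < 2) stop_f("need at least 2 candidate orders")
  if (!is_number(eps_max) || eps_max <= 0) stop_f("`eps_max` must be > 0")
  if (!is_number(eps_points) || eps_points < 5) stop_f("`eps_points` must be >= 5")

  ref_fits <- lapply(candidate_orders, function(nc) {
    lapply(replicates, fit_hill, n_fit = nc, options = options)
  })
  names(ref_fits) <- as.character(candidate_orders)

  repeat {
    grid <- seq(0, eps_max, length.out = eps_points)
    curves <- lapply(seq_along(candidate_orders), function(ci) {
      lapply(seq_along(replicates), function(ri) {
        rho_curve(replicates[[ri]], candidate_orders[ci], family, grid,
                  options = options, ref_fit = ref_fits[[ci]][[ri]],
                  replicate_index = ri - 1L)
      })
    })
    bands <- lapply(curves, aggregate_replicates)
    steady <- vapply(bands, steady_state_reached, logical(1),
                     window_fraction = window_fraction)
    if (!extend || all(steady) || eps_max * 2 > eps_cap) break
    eps_max <- eps_max * 2
  }
  verdict <- symmetry_selection(bands, window_fraction = window_fraction)
  structure(list(verdict = verdict, bands = bands, curves = curves,
                 ref_fits = ref_fits, eps_max_used = eps_max,
                 candidate_orders = candidate_orders, family = family),
            class = "symmetry_selection_result")
}

#' @export
print.symmetry_selection_result <- function(x, ...) {
  cat(sprintf("Symmetry selection (%s family, eps in [0, %g], %d candidates)\n",
              x$family, x$eps_max_used, length(x$candidate_orders)))
  print(x$verdict)
  invisible(x)
}

#' Translation-symmetry consistency check
#'
#' Runs the full transform-fit-invert pipeline with the time-translation
#' family, which is a symmetry of every Hill order, so no candidate should
#' gain or lose fit quality: the replicate-averaged relative residual
#' Delta(epsilon) is expected to vanish within numerical error for every
#' candidate. A non-zero Delta here would indicate a defect in the
#' pipeline rather than a property of the data.
#'
#' @param design a [simulation_design()] (replicates are generated from it).
#' @param candidate_orders candidate orders to check.
#' @param eps_max,eps_points epsilon grid (uniform from 0).
#' @param options a [fit_options()].
#' @return A list with one element per candidate: a `delta_curve` whose
#'   `delta` is the pointwise mean over replicates (attribute
#'   `replicate_deltas` keeps the per-replicate curves).
#' @export
validate_translation <- function(design, candidate_orders = c(1, 2, 3),
                                 eps_max = 5, eps_points = 25L,
                                 options = fit_options()) {
  stopifnot(inherits(design, "simulation_design"))
  replicates <- generate_replicates(design)
  grid <- seq(0, eps_max, length.out = eps_points)
  out <- lapply(candidate_orders, function(nc) {
    per_rep <- lapply(replicates, function(srs) {
      cv <- rho_curve(srs, nc, "translation", grid, options = options)
      delta_curve(cv)
    })
    mean_delta <- rowMeans(do.call(cbind, lapply(per_rep, `[[`, "delta")))
    structure(list(candidate_order = nc, family = "translation",
                   eps_grid = grid, delta = mean_delta),
              class = "delta_curve", replicate_deltas = per_rep)
  })
  names(out) <- as.character(candidate_orders)
  out
}
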