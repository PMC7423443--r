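# The transform-fit-invert statistic and the selection machinery.

test_that("rho(0) reproduces the classical rho0", {
  srs <- generate_series(noisy_design(2, seed = 11), 0)
  for (nc in 1:3) {
    fit <- fit_hill(srs, nc, fast_options())
    r0 <- as.numeric(rho_at_eps(srs, nc, "hill", 0, fit, fast_options()))
    expect_lt(abs(r0 - fit$rho0) / fit$rho0, 1e-8)
    rt <- as.numeric(rho_at_eps(srs, nc, "translation", 0, fit, fast_options()))
    expect_lt(abs(rt - fit$rho0) / fit$rho0, 1e-8)
  }
})

test_that("the matching candidate's rho(eps) is invariant on noiseless data", {
  for (n in 1:3) {
    srs <- noiseless_series(n)
    fit <- fit_hill(srs, n, fast_options())
    cv <- rho_curve(srs, n, "hill", seq(0, 4, length.out = 6),
                    fast_options(), ref_fit = fit)
    expect_true(all(cv$rho < 1e-5))
  }
})

test_that("wrong candidates deteriorate on noiseless data, true stays 10x below", {
  srs <- noiseless_series(2)
  grid <- seq(0, 2, length.out = 5)
  fits <- lapply(1:3, function(nc) fit_hill(srs, nc, fast_options()))
  rho3 <- rho_curve(srs, 3, "hill", grid, fast_options(), ref_fit = fits[[3]])$rho
  expect_true(all(diff(rho3) > 0))          # strictly increasing
  rho2 <- rho_curve(srs, 2, "hill", grid, fast_options(), ref_fit = fits[[2]])$rho
  rho1 <- rho_curve(srs, 1, "hill", grid, fast_options(), ref_fit = fits[[1]])$rho
  expect_gt(rho1[length(grid)], rho1[1] - 1e-12)   # last entry not below first
  expect_gt(min(rho1[5], rho3[5]) / max(rho2[5], 1e-12), 10)
})

test_that("translation-family curves are flat for every candidate", {
  srs <- generate_series(noisy_design(3, seed = 5), 0)
  for (nc in 1:3) {
    fit <- fit_hill(srs, nc, fast_options())
    cv <- rho_curve(srs, nc, "translation", seq(0, 5, length.out = 5),
                    fast_options(), ref_fit = fit)
    expect_lt(max(abs(cv$rho / cv$rho[1] - 1)), 1e-6)
  }
  # noiseless: flat to the same tolerance near zero residual
  s0 <- noiseless_series(2)
  f0 <- fit_hill(s0, 2, fast_options())
  cv0 <- rho_curve(s0, 2, "translation", seq(0, 5, length.out = 5),
                   fast_options(), ref_fit = f0)
  expect_lt(max(cv0$rho), 1e-5)
})

test_that("rho_curve validates its grid and reuses the reference fit", {
  srs <- generate_series(noisy_design(1, seed = 8), 0)
  expect_error(rho_curve(srs, 1, "hill", c(0.5, 1)), "increase from 0")
  expect_error(rho_curve(srs, 1, "hill", c(0, 0.5, 0.4)), "increase from 0")
  fit <- fit_hill(srs, 1, fast_options())
  single <- rho_curve(srs, 1, "hill", 0, fast_options(), ref_fit = fit)
  expect_length(single$rho, 1)
  expect_lt(abs(single$rho[1] - fit$rho0) / fit$rho0, 1e-8)
})

test_that("replicate aggregation computes pointwise means and standard errors", {
  sc <- hill_scaling(benchmark_model(1))
  mk <- function(rho, rep) structure(
    list(candidate_order = 1, family = "hill", eps_grid = c(0, 1, 2),
         rho = rho, rho0 = rho[1], ref_fit = NULL, replicate_index = rep),
    class = "rho_curve")
  band <- aggregate_replicates(list(mk(c(1, 1, 1), 0), mk(c(3, 3, 3), 1)))
  expect_equal(band$mean_rho, c(2, 2, 2))
  expect_equal(band$se_rho, c(1, 1, 1))        # sd = sqrt(2), / sqrt(2)
  one <- aggregate_replicates(list(mk(c(1, 2, 3), 0)))
  expect_equal(one$se_rho, c(0, 0, 0))
  expect_equal(one$mean_rho, c(1, 2, 3))
  # permutation invariance and non-finite exclusion
  b2 <- aggregate_replicates(list(mk(c(3, 3, 3), 1), mk(c(1, 1, 1), 0)))
  expect_equal(b2$mean_rho, band$mean_rho)
  b3 <- aggregate_replicates(list(mk(c(1, NA, 1), 0), mk(c(3, 3, 3), 1)))
  expect_equal(b3$mean_rho[2], 3)
  expect_equal(b3$n_eff, c(2L, 1L, 2L))
  expect_error(aggregate_replicates(list(mk(c(1, 1, 1), 0),
                                         structure(list(candidate_order = 2,
                                                        family = "hill",
                                                        eps_grid = c(0, 1, 2),
                                                        rho = c(1, 1, 1)),
                                                   class = "rho_curve"))),
               "share")
})

test_that("delta curves implement rho/rho0 - 1 and refuse rho0 = 0", {
  mk <- function(rho) structure(
    list(candidate_order = 2, family = "translation", eps_grid = c(0, 1),
         rho = rho, rho0 = rho[1]), class = "rho_curve")
  expect_equal(delta_curve(mk(c(2, 2)))$delta, c(0, 0))
  expect_equal(delta_curve(mk(c(2, 4)))$delta, c(0, 1))
  expect_error(delta_curve(mk(c(0, 0))), "> 0")
})

test_that("steady-state detection matches its defining window rule", {
  mk_band <- function(mean_rho) structure(
    list(candidate_order = 1, family = "hill",
         eps_grid = seq(0, 10, length.out = length(mean_rho)),
         mean_rho = mean_rho, se_rho = rep(0, length(mean_rho)),
         n_eff = rep(1L, length(mean_rho)), n_replicates = 1),
    class = "banded_curve")
  expect_true(steady_state_reached(mk_band(rep(2, 50))))
  expect_false(steady_state_reached(mk_band(seq(0, 10, length.out = 50))))
  eps <- seq(0, 10, length.out = 50)
  expect_true(steady_state_reached(mk_band(1 - exp(-eps))))
  expect_error(steady_state_reached(mk_band(c(1, 1, 1))), "at least 5")
})

test_that("band separation rules select, reject and abstain correctly", {
  grid <- seq(0, 10, length.out = 25)
  mk_band <- function(order, mean, se) structure(
    list(candidate_order = order, family = "hill", eps_grid = grid,
         mean_rho = rep(mean, 25), se_rho = rep(se, 25),
         n_eff = rep(5L, 25), n_replicates = 5), class = "banded_curve")
  # disjoint constant bands: lower one selected
  v <- symmetry_selection(list(mk_band(1, 1, 0.1), mk_band(2, 2, 0.1)))
  expect_equal(v$selected_order, 1)
  expect_equal(v$rejected_orders, 2)
  # identical bands: no selection, all indistinguishable
  v2 <- symmetry_selection(list(mk_band(1, 1, 0.1), mk_band(2, 1, 0.1),
                                mk_band(3, 1, 0.1)))
  expect_true(is.na(v2$selected_order))
  expect_setequal(v2$indistinguishable_orders, c(1, 2, 3))
  # mixed: best separated from one, overlapping another
  v3 <- symmetry_selection(list(mk_band(1, 1, 0.1), mk_band(2, 1.1, 0.1),
                                mk_band(3, 3, 0.1)))
  expect_true(is.na(v3$selected_order))
  expect_setequal(v3$indistinguishable_orders, c(1, 2))
  expect_equal(v3$rejected_orders, 3)
  # a band with no finite window values is rejected with a diagnostic
  bad <- mk_band(3, NaN, 0.1)
  v4 <- symmetry_selection(list(mk_band(1, 1, 0.1), mk_band(2, 2, 0.1), bad))
  expect_equal(v4$selected_order, 1)
  expect_true(3 %in% v4$rejected_orders)
  expect_match(paste(v4$diagnostics, collapse = " "), "no finite")
  # verdict partition covers all candidates
  all_orders <- c(v3$selected_order[!is.na(v3$selected_order)],
                  v3$rejected_orders, v3$indistinguishable_orders)
  expect_setequal(all_orders, c(1, 2, 3))
})

test_that("translation validation yields near-zero Delta at sigma = 0", {
  d0 <- default_design(2, noise = noise_model(0), n_replicates = 1L)
  deltas <- validate_translation(d0, c(1, 2, 3), eps_max = 3, eps_points = 7)
  for (dc in deltas) {
    expect_equal(dc$delta[1], 0, tolerance = 1e-12)
    expect_lt(max(abs(dc$delta)), 1e-6)
  }
})

test_that("range extension doubles until steady state or the cap", {
  reps <- generate_replicates(default_design(1, master_seed = 13,
                                             n_replicates = 2L))
  # translation curves are flat, so the initial range is already steady
  res <- run_symmetry_selection(reps, c(1, 2), family = "translation",
                                eps_max = 2, eps_points = 8,
                                options = fast_options(), extend = TRUE)
  expect_equal(res$eps_max_used, 2)
  expect_true(all(vapply(res$bands, steady_state_reached, logical(1))))
})
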