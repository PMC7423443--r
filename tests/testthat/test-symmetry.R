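# Point transformations: group structure, action on series, and the
# first-integral closure oracle.

test_that("pointwise action matches hand-evaluated images", {
  expect_equal(apply_point(point_transform("hill", 0, order = 1), 1.0, 0.5),
               list(tau = 1.0, y = 0.5))                       # identity at eps = 0
  expect_equal(apply_point(point_transform("hill", log(2), order = 2), 0, 1),
               list(tau = -1.5, y = 2))
  expect_equal(apply_point(point_transform("translation", 3), 1, 0.5),
               list(tau = 4, y = 0.5))
})

test_that("inverse and composition satisfy the one-parameter group law", {
  set.seed(7)
  pts <- list(tau = runif(20, -2, 5), y = runif(20, 0.05, 8))
  for (fam in c("translation", "hill")) for (ord in 1:3) {
    if (fam == "translation" && ord > 1) next
    o <- if (fam == "hill") ord else NULL
    a <- point_transform(fam, 0.37, o)
    b <- point_transform(fam, -1.21, o)
    ab <- compose_transforms(a, b)
    expect_equal(ab$epsilon, 0.37 - 1.21)
    seq_img <- apply_point(b, apply_point(a, pts$tau, pts$y)$tau,
                           apply_point(a, pts$tau, pts$y)$y)
    one_img <- apply_point(ab, pts$tau, pts$y)
    expect_lt(max(abs(seq_img$tau - one_img$tau),
                  abs(seq_img$y - one_img$y)), 1e-10)
    # inverse round trip
    inv <- invert_transform(a)
    expect_equal(inv$epsilon, -0.37)
    back <- apply_point(inv, apply_point(a, pts$tau, pts$y)$tau,
                        apply_point(a, pts$tau, pts$y)$y)
    expect_lt(max(abs(back$tau - pts$tau), abs(back$y - pts$y)), 1e-12)
  }
  expect_error(compose_transforms(point_transform("translation", 1),
                                  point_transform("hill", 1, order = 1)),
               "family or order")
  expect_error(compose_transforms(point_transform("hill", 1, order = 1),
                                  point_transform("hill", 1, order = 2)),
               "family or order")
})

test_that("transform_series re-sorts by transformed time and carries scaling", {
  sc <- hill_scaling(benchmark_model(2))
  ds <- dimensionless_series(c(0, 1, 2), c(3, 2, 1), sc)
  idt <- transform_series(point_transform("hill", 0, order = 2), ds)
  expect_equal(idt$tau, ds$tau)
  expect_equal(idt$y, ds$y)
  shifted <- transform_series(point_transform("translation", 2), ds)
  expect_equal(shifted$tau, c(2, 3, 4))
  expect_equal(shifted$y, ds$y)
  expect_identical(shifted$scaling, sc)

  # craft a 2-point series whose hill image reverses ordering: needs the
  # transformed times out of order before sorting
  tr <- point_transform("hill", 3, order = 2)
  ds2 <- dimensionless_series(c(0, 0.1), c(0.1, 0.09), sc)
  img <- apply_point(tr, ds2$tau, ds2$y)
  out <- transform_series(tr, ds2)
  expect_equal(out$tau, sort(img$tau))
  expect_true(all(diff(out$tau) > 0))

  # coincident transformed times -> degenerate-transform error. For order 1
  # the image time is tau + y (1 - e^eps); with points (0,1) and (1,2) both
  # images land at -1 exactly when eps = log 2.
  sc1 <- hill_scaling(benchmark_model(1))
  ds3 <- dimensionless_series(c(0, 1), c(1, 2), sc1)
  expect_error(transform_series(point_transform("hill", log(2), order = 1), ds3),
               "degenerate")
  expect_s3_class(transform_series(point_transform("hill", 0.3, order = 1), ds3),
                  "dimensionless_series")
})

test_that("first-integral scaling law holds along transformed trajectories", {
  # under the order-n transform, C -> C + eps (n = 1) and
  # C -> e^{-(n-1) eps} C (n >= 2); verified along integrated trajectories
  for (n in 1:3) for (eps in c(-0.4, 0.5, 1.3)) {
    y0 <- 3.65
    tau_end <- first_integral(n, 0, y0) - first_integral(n, 0, 0.1 * y0)
    tg <- seq(0, tau_end, length.out = 128)
    y <- solve_dimensionless(n, y0, tg, rtol = 1e-12, atol = 1e-14)
    img <- apply_point(point_transform("hill", eps, order = n), tg, y)
    C0 <- first_integral(n, tg, y)
    C1 <- first_integral(n, img$tau, img$y)
    expected <- if (n == 1) C0 + eps else exp(-(n - 1) * eps) * C0
    expect_lt(max(abs(C1 - expected)), 1e-6)
  }
})

test_that("symmetry defect separates matching from mismatched orders", {
  for (m in 1:3) for (n in 1:3) {
    d <- symmetry_defect(m, n, epsilon = 0.5, y0 = 3.65)
    if (m == n) expect_lt(d, 1e-6) else expect_gt(d, 1e-2)
  }
  # identity and translation are symmetries of every order
  for (n in 1:3) {
    expect_lt(symmetry_defect(n, n, epsilon = 0, y0 = 2), 1e-10)
    expect_lt(symmetry_defect(1, n, epsilon = 0.8, y0 = 2,
                              family = "translation"), 1e-10)
  }
})
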