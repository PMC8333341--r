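test_that("forward model matches hand-derived values and limits", {
  # vertical force: no polarization dependence, I = i_max at any alpha/phi
  for (a in c(0, 33, 120)) expect_equal(forward_intensity(12, 0, 100, a), 100)
  # pure in-plane force with b = 0: E parallel to F gives zero
  expect_equal(forward_intensity(77, 90, 100, 77, b = 0), 0)
  # direct evaluation: A = 93.1, c = 6.9, I = 93.1 sin^2(60) + 6.9
  expect_equal(forward_intensity(30, 90, 100, 90),
               93.1 * sin(pi / 3)^2 + 6.9)
  # periodic in alpha with period 180
  expect_equal(forward_intensity(41, 62, 850, 13),
               forward_intensity(41, 62, 850, 13 + 180))
})

test_that("three-point fit inverts the forward model exactly", {
  f <- fit_three_point(125, 50, 125, alpha_triplet(17, 77, 137))
  expect_equal(f$phi, 77)
  expect_equal(f$A, 100)
  expect_equal(f$c, 50)
  expect_equal(f$i_max, 150)
  # values quoted to 2 decimals, so compare loosely
  f2 <- fit_three_point(24.05, 62.79, 93.16, alpha_triplet(17, 77, 137))
  expect_lt(axial_dist(f2$phi, 30), 1e-3)
  expect_equal(f2$A, 80, tolerance = 1e-4)
  expect_equal(f2$c, 20, tolerance = 1e-3)

  # exact-interpolation property on random draws, default instrument triplet
  set.seed(11)
  for (i in 1:300) {
    phi <- runif(1, 0, 180); A <- runif(1, 0.5, 500); cc <- runif(1, 0, 200)
    ii <- vapply(as.numeric(alpha_triplet()), function(a)
      A * sin((a - phi) * pi / 180)^2 + cc, numeric(1))
    g <- fit_three_point(ii[1], ii[2], ii[3])
    expect_axial_equal(g$phi, phi, 1e-8)
    expect_equal(g$A, A, tolerance = 1e-10)
    expect_equal(g$c, cc, tolerance = 1e-9)
    expect_true(g$orientation_defined)
  }
})

test_that("constant input gives orientation-undefined fit with A = 0", {
  f <- fit_three_point(100, 100, 100, alpha_triplet(17, 77, 137))
  expect_equal(f$A, 0)
  expect_equal(f$c, 100)
  expect_equal(f$i_max, 100)
  expect_false(f$orientation_defined)
  expect_true(is.na(f$phi))
})

test_that("fit is covariant under a common rotation of alphas and phi", {
  set.seed(4)
  for (i in 1:50) {
    phi <- runif(1, 0, 180); A <- runif(1, 1, 100); cc <- runif(1, 0, 50)
    delta <- runif(1, -90, 90)
    base <- c(17, 77, 137)
    ii <- A * sin((base - phi) * pi / 180)^2 + cc
    ii_s <- A * sin((base + delta - (phi + delta)) * pi / 180)^2 + cc
    f0 <- fit_three_point(ii[1], ii[2], ii[3],
                          alpha_triplet(base[1], base[2], base[3]))
    f1 <- fit_three_point(ii_s[1], ii_s[2], ii_s[3],
                          do.call(alpha_triplet, as.list(base + delta)))
    expect_equal(f1$A, f0$A, tolerance = 1e-9)
    expect_equal(f1$c, f0$c, tolerance = 1e-9)
    expect_axial_equal(f1$phi, f0$phi + delta, 1e-7)
  }
})

test_that("closed-form fit agrees with the dense least-squares oracle", {
  set.seed(7)
  for (i in 1:200) {
    phi <- runif(1, 0, 180); A <- runif(1, 0.5, 300); cc <- runif(1, 0, 100)
    ora <- ls_fit_dense(phi, A, cc)
    ii <- vapply(as.numeric(alpha_triplet()), function(a)
      A * sin((a - phi) * pi / 180)^2 + cc, numeric(1))
    f <- fit_three_point(ii[1], ii[2], ii[3])
    expect_lt(axial_dist(f$phi, ora$phi), 1e-6)
    expect_equal(f$A, ora$A, tolerance = 1e-8)
  }
})

test_that("tilt recovery matches the inverse relation and boundaries", {
  expect_equal(theta_from_fit(0, 100)$theta, 0)          # c/i_max = 1
  expect_equal(theta_from_fit(93.1, 6.9)$theta, 90)      # c/i_max = b
  expect_equal(theta_from_fit(46.55, 53.45)$theta, 45)
  # strictly decreasing in c at fixed i_max
  cs <- seq(8, 99, by = 1)
  th <- theta_from_fit(100 - cs, cs)$theta
  expect_true(all(diff(th) < 0))
  # invalid inputs
  bad <- theta_from_fit(c(10, 110), c(-5, -10))
  expect_true(all(is.na(bad$theta)))
  expect_false(any(bad$valid))
  # out-of-range arguments are clipped and counted
  clip <- theta_from_fit(98, 2)   # c/i_max = 0.02 < b
  expect_equal(clip$theta, 90)
  expect_equal(clip$n_clipped, 1L)
})

test_that("per-image fitting recovers a uniform scene and masks dim pixels", {
  trip <- make_truth_triplet(matrix(45, 8, 8), matrix(90, 8, 8),
                             matrix(1000, 8, 8))
  map <- fit_image_triplet(trip, mask_quantile = 0)
  expect_axial_equal(map$phi, 45, 1e-8)
  expect_equal(unique(as.numeric(map$theta)), 90, tolerance = 1e-8)
  expect_equal(unique(as.numeric(map$i_max)), 1000, tolerance = 1e-8)
  expect_true(all(map$valid))
  # i_max is independent of phi for fixed (theta, i_max)
  phis <- matrix(seq(0, 179, length.out = 64), 8, 8)
  trip2 <- make_truth_triplet(phis, matrix(70, 8, 8), matrix(500, 8, 8))
  map2 <- fit_image_triplet(trip2, mask_quantile = 0)
  expect_lt(diff(range(map2$i_max)), 1e-9)

  # all-zero images: every pixel invalid
  zero <- polarization_triplet(replicate(3, matrix(0, 6, 6),
                                         simplify = FALSE))
  expect_true(all(!fit_image_triplet(zero)$valid))

  # default 60th-percentile mask drops the dim half of a two-level scene
  imax <- matrix(100, 10, 10); imax[, 1:5] <- 5
  trip3 <- make_truth_triplet(matrix(30, 10, 10), matrix(80, 10, 10), imax)
  map3 <- fit_image_triplet(trip3)   # threshold = 60th pct of i_max
  expect_true(all(map3$valid[, 6:10]))
  expect_false(any(map3$valid[, 1:5]))

  expect_error(polarization_triplet(list(matrix(0, 2, 2), matrix(0, 2, 2),
                                         matrix(0, 3, 3))),
               "dimensions")
})

test_that("polarization response summarizes amplitude vs offset by region", {
  mk <- function(A, cc) {
    n <- 6
    orientation_map(matrix(10, n, n), matrix(45, n, n), matrix(A, n, n),
                    matrix(cc, n, n), matrix(A + cc, n, n),
                    matrix(TRUE, n, n))
  }
  cellm <- matrix(FALSE, 6, 6); cellm[1:3, ] <- TRUE
  bgm <- !cellm
  # A = 0 everywhere -> response 0 in both regions
  r0 <- polarization_response(mk(0, 7), cellm, bgm, normalize = FALSE)
  expect_equal(r0$cell, 0)
  # uniform A = 10, c = 4 -> 10 / (4 + 1) = 2
  r1 <- polarization_response(mk(10, 4), cellm, bgm, normalize = FALSE)
  expect_equal(r1$cell, 2)
  expect_error(polarization_response(mk(1, 1), matrix(FALSE, 6, 6), bgm),
               "nonempty")
  expect_error(polarization_response(mk(1, 1), cellm, cellm), "disjoint")
})

test_that("polarized platelet scene scores far above flat background", {
  sc <- make_platelet_scene(radius_um = 1.2, n_lobes = 2, seed = 9,
                            theta_sd = 0, theta_mean = 90)
  m <- render_montage(sc, noise = noise_model(seed = 10))
  map <- process_montage(m, mask_quantile = 0)
  cellm <- sc$i_max > 0
  bgm <- !cellm
  r <- polarization_response(map, cellm, bgm)
  expect_gt(r$cell, 10 * max(r$background, 0.01))
})

test_that("alpha triplets are validated and reduced", {
  a <- alpha_triplet(197, 77, 137)  # 197 reduces to 17
  expect_equal(as.numeric(a)[1], 17)
  expect_error(alpha_triplet(0, 50, 120), "60 degrees")
  expect_error(dipole_params(b = 1.2))
})
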