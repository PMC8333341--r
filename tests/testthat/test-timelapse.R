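test_that("alignment parameter reproduces the circular-statistics identities", {
  expect_equal(alignment_parameter(rep(33, 7)), 1)
  expect_equal(alignment_parameter(seq(0, 175, by = 5)), 0, tolerance = 1e-12)
  expect_equal(alignment_parameter(c(rep(0, 5), rep(45, 5))), sqrt(2) / 2)
  # invariant under a global rotation of all angles
  set.seed(12)
  phis <- runif(200, 0, 180)
  for (delta in c(10, 45, 133))
    expect_equal(alignment_parameter(phis + delta),
                 alignment_parameter(phis), tolerance = 1e-12)
  # weighting: zero-weight pixels are ignored
  expect_equal(alignment_parameter(c(0, 90), weights = c(1, 0)), 1)
  expect_error(alignment_parameter(c(NA, NA)), "no valid")
})

test_that("tension-area model and measurement behave as constructed", {
  # t -> infinity returns to the basal value T0
  expect_equal(model_tension_area(1e6, 20, 5, 20, 1.7, 5, 0.3), 0.3,
               tolerance = 1e-9)
  # empty image
  expect_equal(tension_area(matrix(0, 8, 8), threshold = 10), 0)
  # 100 supra-threshold pixels at 60 nm/px -> 0.36 um^2
  img <- matrix(0, 20, 20); img[1:10, 1:10] <- 50
  expect_equal(tension_area(img, threshold = 10, pixel_size_nm = 60), 0.36)
  # background-rule threshold on a synthetic platelet recovers mask area
  sc <- make_platelet_scene(radius_um = 1.2, n_lobes = 2, seed = 1)
  m <- render_montage(sc, noise = noise_model(seed = 2))
  map <- process_montage(m, subtract_percentile = FALSE, mask_quantile = 0)
  bg <- matrix(FALSE, nrow(sc$phi), ncol(sc$phi)); bg[1:4, ] <- TRUE
  area <- tension_area(map, background_mask = bg)
  true_area <- sum(sc$i_max > 0) * (60 / 1000)^2
  expect_equal(area, true_area, tolerance = 0.05)
  expect_error(tension_area(img), "threshold")
})

test_that("drift correction recovers known shifts", {
  set.seed(31)
  base <- matrix(0, 48, 48)
  base[15:30, 18:33] <- matrix(runif(256, 500, 1500), 16, 16)
  stack <- lapply(0:5, function(k)
    polforce:::shift_matrix(base, 3 * k, -2 * k) + rnorm(48 * 48, 0, 5))
  dc <- drift_correct(stack)
  truth <- cbind(3 * (0:5), -2 * (0:5))
  expect_lt(max(abs(dc$shifts - truth)), 0.5)
  # zero drift
  still <- replicate(4, base, simplify = FALSE)
  expect_equal(drift_correct(still)$shifts, matrix(0, 4, 2))
  # single frame: identity
  one <- drift_correct(list(base))
  expect_identical(one$stack[[1]], base)
  # flat frames: warning, zero shift
  expect_warning(drift_correct(list(matrix(1, 8, 8), matrix(1, 8, 8))),
                 "flat frame")
})

test_that("photobleach correction fits and removes exponential decay", {
  bg <- matrix(FALSE, 24, 24); bg[1:6, ] <- TRUE
  t <- seq(0, 40, by = 2)
  # constant background: factor 1 everywhere (no-op path)
  stack0 <- lapply(t, function(x) matrix(100, 24, 24))
  r0 <- suppressWarnings(photobleach_correct(stack0, bg, t))
  expect_equal(r0$factor, rep(1, length(t)))
  # known decay: tau recovered within 5%, corrected background flat
  set.seed(7)
  stack1 <- lapply(t, function(x)
    matrix(200 * exp(-x / 15), 24, 24) + rnorm(24 * 24, 0, 1))
  r1 <- photobleach_correct(stack1, bg, t)
  expect_equal(r1$tau, 15, tolerance = 0.05)
  bgm <- vapply(r1$stack, function(m) mean(m[bg]), numeric(1))
  expect_lt(diff(range(bgm)) / mean(bgm), 0.05)
  # increasing background: warning, no-op
  stack2 <- lapply(t, function(x) matrix(100 + 2 * x, 24, 24))
  expect_warning(photobleach_correct(stack2, bg, t), "does not decay")
})

test_that("spreading fit recovers noise-free kinetics within 2%", {
  t <- seq(0, 82, by = 2)
  truth <- c(T_max = 20, t_attach = 6, t_detach = 20, tau_spread = 1.7,
             tau_retract = 5, T0 = 0.5)
  Tv <- model_tension_area(t, 20, 6, 20, 1.7, 5, 0.5)
  fit <- fit_spreading(platelet_track(t, Tv), seed = 1)
  got <- unlist(fit[names(truth)])
  expect_lt(max(abs(got - truth) / truth), 0.02)
  expect_false(fit$flagged)
  # degenerate all-zero track
  z <- fit_spreading(platelet_track(t, rep(0, length(t))), seed = 1)
  expect_equal(z$T_max, 0)
  expect_true(z$flagged)
})

test_that("alignment fit recovers parameters and classifies trends", {
  t <- seq(0, 82, by = 2)
  Rv <- model_alignment(t, 0.2, 0.7, 5, 6)
  Rv[t < 6] <- 0.2
  track <- platelet_track(t, rep(1, length(t)), pmin(pmax(Rv, 0), 1))
  fit <- fit_alignment(track, t_attach = 6, t_detach = 40)
  expect_equal(fit$R0, 0.2, tolerance = 0.05)
  expect_equal(fit$R_max, 0.7, tolerance = 0.05)
  expect_equal(fit$tau_align, 5, tolerance = 0.05 * 5)
  expect_equal(fit$trend, "increasing")
  expect_equal(fit$delta_R, fit$R_max - fit$R0)
  # constant R: no significant trend
  flatR <- platelet_track(t, rep(1, length(t)), rep(0.4, length(t)))
  expect_equal(fit_alignment(flatR, 6, 40)$trend, "none")
  # decreasing R
  dec <- platelet_track(t, rep(1, length(t)),
                        pmin(pmax(0.8 - 0.006 * t, 0), 1))
  expect_equal(fit_alignment(dec, 6, 60)$trend, "decreasing")
  # window too short
  short <- fit_alignment(track, t_attach = 6, t_detach = 2)
  expect_equal(short$trend, "unclassifiable")
})

test_that("noisy synthetic cohort recovers kinetics at the population level", {
  set.seed(100)
  t <- seq(0, 82, by = 2)
  n <- 20
  rel_err <- matrix(NA, n, 2)
  for (i in seq_len(n)) {
    tmax <- runif(1, 12, 28); tsp <- runif(1, 1.2, 3)
    ta <- runif(1, 4, 12); td <- runif(1, 15, 25)
    Tv <- model_tension_area(t, tmax, ta, td, tsp, 5, 0.5) +
      rnorm(length(t), 0, 0.5)
    fit <- fit_spreading(platelet_track(t, pmax(Tv, 0)), seed = 200 + i)
    rel_err[i, ] <- abs(c(fit$T_max - tmax, fit$tau_spread - tsp)) /
      c(tmax, tsp)
  }
  # regression guard: tau_spread ~ sampling interval makes this the
  # hardest parameter; the oracle-start LS error at this noise is ~10%
  expect_lt(median(rel_err[, 1]), 0.15)
  expect_lt(median(rel_err[, 2]), 0.2)
})

test_that("cohort statistics: medians, IQR, rank-sum tests, bootstrap CIs", {
  set.seed(41)
  df <- data.frame(
    group = rep(c("a", "b"), each = 15),
    tau = c(rnorm(15, 1.7, 0.3), rnorm(15, 5.0, 0.8)),
    same = rnorm(30, 10, 1))
  cs <- cohort_stats(df, "group", n_boot = 300, seed = 2)
  expect_true(cs$tests$p_value[cs$tests$parameter == "tau"] < 1e-4)
  expect_true(cs$tests$p_value[cs$tests$parameter == "same"] > 0.05)
  med_a <- cs$summary$median[cs$summary$group == "a" &
                               cs$summary$parameter == "tau"]
  expect_equal(med_a, median(df$tau[df$group == "a"]))
  ci <- cs$summary[cs$summary$group == "b" & cs$summary$parameter == "tau", ]
  expect_true(ci$ci_lo <= ci$median && ci$median <= ci$ci_hi)
  # identical groups: p approximately 1
  df2 <- data.frame(group = rep(c("a", "b"), each = 10), v = rep(1:10, 2))
  cs2 <- cohort_stats(df2, "group", n_boot = 50)
  expect_gt(cs2$tests$p_value[1], 0.5)
  # degenerate groupings are rejected
  expect_error(cohort_stats(data.frame(group = "a", v = 1:3), "group"),
               "two groups")
  expect_error(cohort_stats(data.frame(group = c("a", "a", "b"), v = 1:3),
                            "group"), "two members")
})

test_that("linescan FWHM matches the Gaussian closed form", {
  d <- 61; sigma <- 3
  img <- matrix(0, d, d)
  for (i in 1:d) img[i, ] <- 1000 * exp(-((i - 31)^2) / (2 * sigma^2))
  w <- measure_edge_width(img, from = c(5, 31), to = c(57, 31),
                          pixel_size_nm = 60)
  expect_equal(w$width_nm, 2.3548 * sigma * 60, tolerance = 0.05)
  # smoothing widens the measured ridge
  sm <- smooth_disk(img, 4)
  w2 <- measure_edge_width(sm, from = c(5, 31), to = c(57, 31),
                           pixel_size_nm = 60)
  expect_gt(w2$width_nm, w$width_nm)
  # flat profile: no peak
  expect_error(measure_edge_width(matrix(1, 20, 20), c(2, 10), c(18, 10)),
               "no ridge")
})

test_that("image-level timelapse recovers schedule parameters", {
  sch <- timelapse_schedule(T_max = 20, t_attach = 6, t_detach = 20,
                            tau_spread = 1.7, tau_retract = 5)
  tl <- render_timelapse(sch, duration_min = 60, dim_px = 64,
                         pixel_size_nm = 120, noise = noise_model(seed = 7))
  maps <- lapply(tl$montages, process_montage, subtract_percentile = FALSE,
                 mask_quantile = 0)
  bg <- matrix(FALSE, 64, 64); bg[1:6, ] <- TRUE
  trk <- measure_track(maps, tl$time_min, background_mask = bg)
  sf <- fit_spreading(trk, seed = 3)
  expect_equal(sf$T_max, 20, tolerance = 0.10)
  expect_equal(sf$t_attach, 6, tolerance = 0.15 * 6)
  expect_equal(sf$tau_spread, 1.7, tolerance = 0.15 * 1.7)
  af <- fit_alignment(trk, sf$t_attach, sf$t_detach)
  expect_equal(af$trend, "increasing")
  expect_equal(af$tau_align, 5, tolerance = 0.3 * 5)
})
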