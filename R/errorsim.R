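#' Monte Carlo characterization of orientation measurement error
#'
#' With only three polarization samples per pixel, shot noise propagates
#' into the recovered (phi, theta) in an orientation-dependent way. The
#' error of the estimator at a true orientation is characterized by
#' simulation: generate the ideal intensities with the forward model,
#' draw Poisson photon noise on each raw phase-stepped frame, average
#' the frames into the polarization triplet (exactly as the acquisition
#' pipeline does), refit, and repeat. Random error epsilon is the mean
#' absolute deviation of the measured value from truth; systematic
#' error sigma is the deviation of the mean measured value from truth.
#' All phi statistics use axial (doubled-angle) conventions, so phi
#' errors never exceed 90 degrees and the mean is wrap-safe.
#'
#' @name polforce-errorsim
#' @keywords internal
NULL

#' Monte Carlo error at one true orientation
#'
#' @param phi,theta true orientation, degrees.
#' @param i_max_photons expected peak intensity, photons.
#' @param n_reps Monte Carlo repetitions. Default 30000.
#' @param alphas [alpha_triplet()].
#' @param b unstacked fraction correction.
#' @param phase_frames raw phase-stepped frames averaged per
#'   polarization image (5 for "3D-SIM", 3 for "2D-SIM"); shot noise is
#'   drawn per raw frame, so the averaged image has variance mu /
#'   `phase_frames`. Set 1 to noise the averaged triplet directly.
#' @param read_sd optional Gaussian read noise sd, counts per averaged
#'   image (default 0: pure shot noise).
#' @param seed RNG seed.
#' @return list: `eps_phi` (= mean axial |phi - phi*|), `sig_phi`
#'   (= phi - axial mean of phi*), `eps_theta`, `sig_theta` (degrees),
#'   plus bookkeeping counts `n_phi`, `n_theta` of usable repetitions.
#' @export
mc_orientation_error <- function(phi, theta, i_max_photons,
                                 n_reps = 30000, alphas = alpha_triplet(),
                                 b = 0.069, phase_frames = 5,
                                 read_sd = 0, seed = NULL) {
  stopifnot(i_max_photons > 0, n_reps >= 1, phase_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- as.numeric(alphas)
  ideal <- forward_intensity(phi, theta, i_max_photons, a, b)
  draw <- function(mu) {
    # sum of phase_frames Poisson frames of mean mu, rescaled to mean mu
    x <- stats::rpois(n_reps, phase_frames * mu) / phase_frames
    if (read_sd > 0) x <- x + stats::rnorm(n_reps, 0, read_sd)
    x
  }
  i1 <- draw(ideal[1]); i2 <- draw(ideal[2]); i3 <- draw(ideal[3])
  fit <- fit_three_point(i1, i2, i3, alphas)
  th <- theta_from_fit(fit$A, fit$c, b)
  phi_star <- fit$phi[fit$orientation_defined]
  theta_star <- th$theta[th$valid]
  list(
    eps_phi = mean(axial_dist(phi, phi_star)),
    sig_phi = axial_diff(phi, axial_mean(phi_star)),
    eps_theta = mean(abs(theta - theta_star)),
    sig_theta = theta - mean(theta_star),
    n_phi = length(phi_star), n_theta = length(theta_star),
    n_clipped = th$n_clipped)
}

#' Error surface over a (phi, theta) grid
#'
#' Evaluates [mc_orientation_error()] on a regular orientation grid at a
#' fixed photon budget.
#'
#' @param i_max_photons peak intensity, photons.
#' @param phi_grid,theta_grid grid values, degrees (>= 4 per axis).
#' @param n_reps repetitions per grid point.
#' @param alphas,b,phase_frames,read_sd forwarded to
#'   [mc_orientation_error()].
#' @param seed base seed; each grid point uses a derived sub-seed so the
#'   surface is reproducible and order-independent.
#' @return an `error_surface`: data frame with one row per grid point
#'   (phi, theta, eps_phi, sig_phi, eps_theta, sig_theta) plus metadata
#'   attributes.
#' @export
build_error_surface <- function(i_max_photons = 1000,
                                phi_grid = seq(0, 165, by = 15),
                                theta_grid = seq(15, 90, by = 15),
                                n_reps = 30000,
                                alphas = alpha_triplet(), b = 0.069,
                                phase_frames = 5, read_sd = 0, seed = 1) {
  stopifnot(length(phi_grid) >= 4, length(theta_grid) >= 4)
  grid <- expand.grid(phi = phi_grid, theta = theta_grid)
  res <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    r <- mc_orientation_error(grid$phi[k], grid$theta[k], i_max_photons,
                              n_reps, alphas, b, phase_frames, read_sd,
                              seed = (seed + 7919L * k) %% .Machine$integer.max)
    res[[k]] <- data.frame(phi = grid$phi[k], theta = grid$theta[k],
                           eps_phi = r$eps_phi, sig_phi = r$sig_phi,
                           eps_theta = r$eps_theta, sig_theta = r$sig_theta)
  }
  out <- do.call(rbind, res)
  attr(out, "i_max_photons") <- i_max_photons
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- c("error_surface", "data.frame")
  out
}

#' Peak-to-peak phi dependence of each error metric
#'
#' For each tilt band of an error surface, the max-minus-min across true
#' phi of each of the four error metrics; the overall maximum summarizes
#' how strongly measurement error depends on the in-plane angle.
#'
#' @param surface an `error_surface`.
#' @return list with `per_theta` (data frame: theta x metric ranges) and
#'   `max_ptp` (degrees, the largest range over metrics and theta).
#' @export
phi_dependence <- function(surface) {
  metrics <- c("eps_phi", "sig_phi", "eps_theta", "sig_theta")
  per <- do.call(rbind, lapply(split(surface, surface$theta), function(d) {
    v <- vapply(metrics, function(m) diff(range(d[[m]])), numeric(1))
    data.frame(theta = d$theta[1], t(v))
  }))
  rownames(per) <- NULL
  list(per_theta = per, max_ptp = max(as.matrix(per[, metrics])))
}

#' Histogram uniformity of recovered phi under a uniform truth
#'
#' Simulates pixels with phi drawn uniformly on [0, 180) (theta fixed,
#' default in-plane), recovers phi through the three-point fit under
#' shot noise, and histograms the recovered values into equal-width
#' bins. An unbiased estimator gives each bin 100/bins percent
#' (2 percent for 50 bins).
#'
#' @param n_pixels simulated pixels (>= bins).
#' @param i_max_photons peak intensity, photons.
#' @param theta true tilt, degrees. Default 90.
#' @param bins histogram bins over [0, 180). Default 50.
#' @param alphas,b forwarded to the model.
#' @param phase_frames raw frames averaged per polarization image (see
#'   [mc_orientation_error()]).
#' @param seed RNG seed.
#' @param noise_free skip the Poisson noise (ideal-recovery check).
#' @param phi_true optional vector of true angles (e.g., a stratified
#'   grid); default: uniform draws on [0, 180).
#' @return list: `freq_pct` per-bin frequencies (percent, summing to
#'   100), `breaks`, `max_dev_pct` max absolute deviation from the
#'   uniform ideal, `ideal_pct`.
#' @export
phi_uniformity_histogram <- function(n_pixels = 1e5, i_max_photons = 1000,
                                     theta = 90, bins = 50,
                                     alphas = alpha_triplet(), b = 0.069,
                                     phase_frames = 5, seed = NULL,
                                     noise_free = FALSE, phi_true = NULL) {
  stopifnot(n_pixels >= bins)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(phi_true)) phi_true <- stats::runif(n_pixels, 0, 180)
  else n_pixels <- length(phi_true)
  a <- as.numeric(alphas)
  ac <- sinusoid_ac(theta, i_max_photons, b)
  ii <- lapply(a, function(al) {
    mu <- ac$A * sin(deg2rad(al - phi_true))^2 + ac$c
    if (noise_free) mu
    else stats::rpois(n_pixels, phase_frames * mu) / phase_frames
  })
  fit <- fit_three_point(ii[[1]], ii[[2]], ii[[3]], alphas)
  phi_star <- fit$phi[fit$orientation_defined]
  breaks <- seq(0, 180, length.out = bins + 1)
  counts <- graphics::hist(phi_star, breaks = breaks, plot = FALSE)$counts
  freq <- 100 * counts / sum(counts)
  ideal <- 100 / bins
  list(freq_pct = freq, breaks = breaks,
       max_dev_pct = max(abs(freq - ideal)), ideal_pct = ideal,
       n_used = length(phi_star))
}

#' Export an error surface to CSV
#' @param surface an `error_surface`.
#' @param path output file.
#' @export
write_error_surface <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}
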