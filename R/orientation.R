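#' @section Dipole intensity model:
#' An opened tension probe holds its fluorophore so that the transition
#' dipole is perpendicular to the force vector F and free to rotate about
#' it, producing a "disk" of dipole orientations. Under linearly polarized
#' excitation at in-plane angle alpha the expected fluorescence at a pixel
#' is
#'
#'   I(alpha) = A * sin^2(alpha - phi) + c
#'
#' where phi is the in-plane force angle (axial, modulo 180), and the
#' amplitude A and offset c are set by the tilt angle theta (measured from
#' the optical axis) and the peak intensity Imax = A + c:
#'
#'   c = Imax * (b + (1 - b) * cos^2 theta)
#'   A = Imax * (1 - b) * sin^2 theta
#'
#' b (default 0.069) corrects for the fraction of time the fluorophore
#' spends unstacked from the duplex terminus and hence randomly oriented.
#'
#' @name polforce-model
#' @keywords internal
NULL

#' Excitation polarization triplet
#'
#' The three stripe/polarization orientations of a SIM acquisition. The
#' closed-form three-point fit requires the angles to be separated by 60
#' degrees modulo 180.
#'
#' @param a1,a2,a3 polarization angles alpha in degrees. Default is the
#'   measured instrument triplet 77, 137, 17.
#' @param tol allowed deviation from exact 60-degree spacing, degrees.
#' @return an `alpha_triplet` numeric vector of length 3 in [0, 180).
#' @export
alpha_triplet <- function(a1 = 77, a2 = 137, a3 = 17, tol = 1e-6) {
  a <- wrap_axial(c(a1, a2, a3))
  seps <- sort(axial_dist(a[c(1, 1, 2)], a[c(2, 3, 3)]))
  if (max(abs(seps - 60)) > tol)
    stop("alpha triplet must be spaced 60 degrees apart (mod 180); got ",
         paste(signif(a, 6), collapse = ", "))
  structure(a, class = "alpha_triplet")
}

#' Dipole model parameters
#'
#' @param b unstacked-fluorophore fraction correction, dimensionless in
#'   [0, 1). Default 0.069.
#' @param undef_tol relative amplitude A/Imax below which the fitted
#'   orientation is treated as undefined (constant-intensity degeneracy).
#' @return a `dipole_params` list.
#' @export
dipole_params <- function(b = 0.069, undef_tol = 1e-3) {
  stopifnot(is.numeric(b), length(b) == 1L, b >= 0, b < 1)
  structure(list(b = b, undef_tol = undef_tol), class = "dipole_params")
}

#' Amplitude and offset of the polarization sinusoid for a given tilt
#'
#' @param theta tilt angle from the optical axis, degrees in [0, 90].
#' @param i_max peak intensity A + c (photons or corrected counts).
#' @param b unstacked fraction correction.
#' @return list with components `A` and `c`.
#' @export
sinusoid_ac <- function(theta, i_max, b = 0.069) {
  st2 <- sin(deg2rad(theta))^2
  list(A = i_max * (1 - b) * st2,
       c = i_max * (b + (1 - b) * (1 - st2)))
}

#' Forward model: expected intensity under polarized excitation
#'
#' Evaluates I = A sin^2(alpha - phi) + c with A, c derived from
#' (theta, i_max, b). Vectorized over all arguments; periodic in alpha with
#' period 180 degrees.
#'
#' @param phi in-plane force angle, degrees (axial).
#' @param theta tilt angle, degrees in [0, 90].
#' @param i_max peak intensity, > 0.
#' @param alpha excitation polarization angle, degrees.
#' @param b unstacked fraction correction.
#' @return expected intensity (same units as `i_max`).
#' @examples
#' forward_intensity(30, 90, 100, 90)     # 93.1 * sin^2(60 deg) + 6.9
#' forward_intensity(12, 0, 100, 45)      # vertical force: always 100
#' @export
forward_intensity <- function(phi, theta, i_max, alpha, b = 0.069) {
  ac <- sinusoid_ac(theta, i_max, b)
  ac$A * sin(deg2rad(alpha - phi))^2 + ac$c
}

#' Closed-form three-point sinusoid fit
#'
#' Recovers the unique (phi, A, c) with A >= 0 such that
#' I = A sin^2(alpha - phi) + c passes through the three measured
#' intensities. Because sin^2 is a pure second harmonic plus a constant,
#' three samples at 60-degree-spaced alpha values determine the sinusoid
#' exactly; the fit is computed by second-harmonic demodulation, which is
#' algebraically identical to the printed arctangent form but free of
#' quadrant ambiguity. Residuals are zero, so the result also equals the
#' least-squares fit.
#'
#' @param i1,i2,i3 measured intensities at `alphas[1..3]`. May be equal
#'   length vectors or matrices (fit runs per element).
#' @param alphas an [alpha_triplet()].
#' @param undef_tol relative amplitude below which phi is flagged
#'   undefined.
#' @return list with elements `phi` (degrees in [0,180), NA where
#'   undefined), `A` (>= 0), `c`, `i_max` (= A + c), and logical
#'   `orientation_defined`. Shapes follow the inputs.
#' @examples
#' fit_three_point(125, 50, 125, alpha_triplet(17, 77, 137))
#' @export
fit_three_point <- function(i1, i2, i3, alphas = alpha_triplet(),
                            undef_tol = 1e-3) {
  if (!inherits(alphas, "alpha_triplet")) alphas <- do.call(alpha_triplet, as.list(alphas))
  stopifnot(length(i2) == length(i1), length(i3) == length(i1))
  e <- exp(2i * deg2rad(as.numeric(alphas)))
  z <- i1 * e[1] + i2 * e[2] + i3 * e[3]
  A <- (4 / 3) * Mod(z)
  avg <- (i1 + i2 + i3) / 3
  cc <- avg - A / 2
  phi <- wrap_axial(rad2deg(Arg(-z)) / 2)
  i_max <- A + cc
  defined <- is.finite(A) & (A > undef_tol * pmax(i_max, 0)) & A > 0
  phi[!defined] <- NA_real_
  out <- list(phi = phi, A = A, c = cc, i_max = i_max,
              orientation_defined = defined)
  if (is.matrix(i1)) out[1:4] <- lapply(out[1:4], function(m) {
    dim(m) <- dim(i1); m
  })
  if (is.matrix(i1)) dim(out$orientation_defined) <- dim(i1)
  out
}

#' Tilt angle from a fitted sinusoid
#'
#' Inverts c / Imax = b + (1 - b) cos^2(theta). Noise can push the
#' argument outside [0, 1]; it is clipped and the number of clipping
#' events is reported (the printed Imax/c variant of this relation does
#' not map onto [0, 90] and is not used; see the package vignette).
#'
#' @param A,c fitted amplitude and offset (vectors or matrices).
#' @param b unstacked fraction correction.
#' @return list with `theta` (degrees in [0, 90]; NA where c <= 0 or
#'   Imax <= 0), logical `valid`, and integer `n_clipped`.
#' @export
theta_from_fit <- function(A, c, b = 0.069) {
  i_max <- A + c
  ratio <- (c / i_max - b) / (1 - b)
  valid <- is.finite(ratio) & (c > 0) & (i_max > 0)
  clipped <- valid & (ratio < 0 | ratio > 1)
  ratio <- pmin(pmax(ratio, 0), 1)
  theta <- rad2deg(acos(sqrt(ratio)))
  theta[!valid] <- NA_real_
  list(theta = theta, valid = valid, n_clipped = sum(clipped))
}

#' Phase-averaged polarization triplet
#'
#' Three co-registered images, one per excitation polarization angle.
#'
#' @param images list of three numeric matrices of equal dimension.
#' @param alphas an [alpha_triplet()] giving the alpha of each image.
#' @param pixel_size_nm pixel size, nanometres.
#' @return a `polarization_triplet` object.
#' @export
polarization_triplet <- function(images, alphas = alpha_triplet(),
                                 pixel_size_nm = 60) {
  stopifnot(is.list(images), length(images) == 3L)
  d <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), d), logical(1))))
    stop("triplet images must share dimensions")
  if (!inherits(alphas, "alpha_triplet")) alphas <- do.call(alpha_triplet, as.list(alphas))
  structure(list(images = images, alphas = alphas,
                 pixel_size_nm = pixel_size_nm),
            class = "polarization_triplet")
}

#' Per-pixel orientation fit of a polarization triplet
#'
#' Applies [fit_three_point()] and [theta_from_fit()] to every pixel and
#' masks dim pixels: pixels whose Imax falls below the `mask_quantile`
#' quantile of the Imax image are marked invalid (default: mask to the
#' 60th percentile).
#'
#' @param triplet a [polarization_triplet()].
#' @param params [dipole_params()].
#' @param mask_quantile quantile of Imax below which pixels are masked,
#'   in [0, 1]. Use 0 to keep everything.
#' @return an `orientation_map`: matrices `phi`, `theta`, `A`, `c`,
#'   `i_max`, `i_avg`, logical `valid`, plus fit metadata.
#' @export
fit_image_triplet <- function(triplet, params = dipole_params(),
                              mask_quantile = 0.60) {
  stopifnot(inherits(triplet, "polarization_triplet"))
  im <- triplet$images
  fit <- fit_three_point(im[[1]], im[[2]], im[[3]], triplet$alphas,
                         undef_tol = params$undef_tol)
  th <- theta_from_fit(fit$A, fit$c, b = params$b)
  i_avg <- (im[[1]] + im[[2]] + im[[3]]) / 3
  thr <- stats::quantile(fit$i_max, mask_quantile, na.rm = TRUE, names = FALSE)
  valid <- th$valid & fit$orientation_defined & (fit$i_max >= thr) &
    (fit$i_max > 0)
  orientation_map(phi = fit$phi, theta = th$theta, A = fit$A, c = fit$c,
                  i_max = fit$i_max, valid = valid, i_avg = i_avg,
                  alphas = triplet$alphas, params = params,
                  mask_quantile = mask_quantile,
                  pixel_size_nm = triplet$pixel_size_nm,
                  n_clipped = th$n_clipped)
}

#' Construct an orientation map
#'
#' Container for per-pixel fit results: in-plane angle phi (degrees,
#' axial), tilt theta (degrees), sinusoid amplitude/offset, Imax, and a
#' validity mask.
#'
#' @param phi,theta,A,c,i_max numeric matrices of equal dimension.
#' @param valid logical matrix; invalid pixels carry no orientation.
#' @param i_avg optional mean-intensity matrix.
#' @param alphas,params,mask_quantile,pixel_size_nm,n_clipped metadata.
#' @return an `orientation_map` object.
#' @export
orientation_map <- function(phi, theta, A, c, i_max, valid,
                            i_avg = NULL, alphas = alpha_triplet(),
                            params = dipole_params(), mask_quantile = NA,
                            pixel_size_nm = 60, n_clipped = 0L) {
  d <- dim(phi)
  for (m in list(theta, A, c, i_max, valid))
    if (!identical(dim(m), d)) stop("orientation_map channels must share dimensions")
  structure(list(phi = phi, theta = theta, A = A, c = c, i_max = i_max,
                 valid = valid, i_avg = i_avg, alphas = alphas,
                 params = params, mask_quantile = mask_quantile,
                 pixel_size_nm = pixel_size_nm, n_clipped = n_clipped),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf("orientation_map: %d x %d pixels, %d valid (%.1f%%)\n",
              d[1], d[2], sum(x$valid), 100 * mean(x$valid)))
  cat(sprintf("  alphas: %s deg; b = %.3f; mask quantile = %s; clipped theta args: %d\n",
              paste(signif(as.numeric(x$alphas), 4), collapse = "/"),
              x$params$b, format(x$mask_quantile), x$n_clipped))
  invisible(x)
}

#' Polarization response of a region
#'
#' Summary statistic <A>/(<c> + 1) over a pixel mask, where <.> is the
#' mean over mask pixels of (optionally background-normalized)
#' amplitude/offset values. Returned for a cell mask and a background
#' mask as a pair, ready for rank-sum testing across cells. A region
#' under oriented tension has large amplitude relative to offset; an
#' unpolarized region scores near zero.
#'
#' @param map an `orientation_map`.
#' @param cell_mask,background_mask disjoint, nonempty logical matrices.
#' @param normalize divide A and c by the background mean Imax before
#'   averaging (the "+1" in the denominator is then in
#'   background-normalized units).
#' @return list with numeric `cell` and `background` responses.
#' @export
polarization_response <- function(map, cell_mask, background_mask,
                                  normalize = TRUE) {
  stopifnot(inherits(map, "orientation_map"))
  if (!any(cell_mask) || !any(background_mask)) stop("masks must be nonempty")
  if (any(cell_mask & background_mask)) stop("masks must be disjoint")
  norm <- if (normalize) mean(map$i_max[background_mask]) else 1
  if (!is.finite(norm) || norm <= 0) norm <- 1
  resp <- function(msk) {
    mean(map$A[msk] / norm) / (mean(map$c[msk] / norm) + 1)
  }
  list(cell = resp(cell_mask), background = resp(background_mask))
}
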