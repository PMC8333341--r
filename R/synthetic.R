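#' Synthetic ground-truth scenes and raw montage rendering
#'
#' Every downstream module is exercised against scenes with known
#' per-pixel (phi, theta, Imax) ground truth: a platelet-like scene (a
#' radially oriented lamellipodial ring plus 0 or 2-4 inner lobes with a
#' common force axis each), a uniform-orientation field, and a
#' bead-phantom ring of tangential in-plane dipoles. Scenes are rendered
#' into raw striped montages through the same forward model the fitting
#' code inverts, with camera baseline, shot noise and optional read
#' noise, photobleaching decay and stage drift.
#'
#' @name polforce-synthetic
#' @keywords internal
NULL

#' Synthetic scene container
#'
#' @param phi,theta,i_max numeric matrices (phi degrees axial, theta
#'   degrees, i_max photons; inactive pixels have i_max 0 and phi NA).
#' @param kind scene kind label.
#' @param pixel_size_nm pixel size.
#' @param extra optional list of construction metadata.
#' @return a `synthetic_scene` object.
#' @export
synthetic_scene <- function(phi, theta, i_max,
                            kind = c("uniform", "platelet", "bead-phantom",
                                     "isotropic"),
                            pixel_size_nm = 60, extra = list()) {
  kind <- match.arg(kind)
  stopifnot(identical(dim(phi), dim(theta)),
            identical(dim(phi), dim(i_max)))
  if (any(i_max < 0)) stop("i_max must be >= 0")
  structure(list(phi = phi, theta = theta, i_max = i_max, kind = kind,
                 pixel_size_nm = pixel_size_nm, extra = extra),
            class = "synthetic_scene")
}

#' Uniform-orientation scene
#'
#' Every pixel carries the same (phi, theta, i_max); handy for exact
#' end-to-end recovery checks.
#'
#' @param dim_px image size (rows = cols).
#' @param phi,theta orientation, degrees.
#' @param i_max peak intensity, photons.
#' @param pixel_size_nm pixel size.
#' @export
make_uniform_scene <- function(dim_px = 32, phi = 45, theta = 90,
                               i_max = 1000, pixel_size_nm = 60) {
  m <- function(v) matrix(v, dim_px, dim_px)
  synthetic_scene(m(wrap_axial(phi)), m(theta), m(i_max), "uniform",
                  pixel_size_nm)
}

# truncated-normal draw on [lo, hi] by rejection (vectors are small)
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Platelet-like tension scene
#'
#' Emulates the traction phenomenology of a spread platelet: an outer
#' lamellipodial ring whose in-plane force angles point radially (toward
#' the centroid), and 0 or 2-4 inner lobes of tension, each lobe sharing
#' a common force axis along its own azimuth. Tilt angles are drawn from
#' a truncated Normal(47, 5) on [0, 90] degrees, matching the tilt range
#' reported for integrin tension, unless overridden.
#'
#' @param radius_um platelet radius, micrometres (> 0).
#' @param n_lobes number of inner tension lobes: 0, 2, 3 or 4.
#' @param ring_width_nm lamellipodial ring width. Default 500.
#' @param i_max_levels named vector: `ring` and `lobe` peak intensities,
#'   photons.
#' @param seed RNG seed for the tilt draws and lobe placement.
#' @param pixel_size_nm pixel size. Default 60.
#' @param dim_px image size; default fits the platelet with a margin.
#' @param theta_mean,theta_sd tilt distribution, degrees; `theta_sd = 0`
#'   gives a deterministic tilt.
#' @return a `synthetic_scene` of kind "platelet"; `extra` records the
#'   centre, ring mask, and per-lobe masks and axes.
#' @export
make_platelet_scene <- function(radius_um = 2.5, n_lobes = 2,
                                ring_width_nm = 500,
                                i_max_levels = c(ring = 1000, lobe = 800),
                                seed = NULL, pixel_size_nm = 60,
                                dim_px = NULL, theta_mean = 47,
                                theta_sd = 5) {
  if (radius_um <= 0) stop("radius must be > 0 (empty scene)")
  if (!n_lobes %in% c(0, 2, 3, 4)) stop("n_lobes must be 0, 2, 3 or 4")
  if (!is.null(seed)) set.seed(seed)
  r_px <- radius_um * 1000 / pixel_size_nm
  if (is.null(dim_px)) dim_px <- ceiling(2 * r_px) + 9L
  ctr <- (dim_px + 1) / 2
  xy <- expand.grid(y = seq_len(dim_px), x = seq_len(dim_px))
  dy <- xy$y - ctr; dx <- xy$x - ctr
  r <- sqrt(dx^2 + dy^2)
  az <- rad2deg(atan2(dy, dx))          # azimuth from centre, degrees
  ring_w_px <- max(1, ring_width_nm / pixel_size_nm)
  ring <- r <= r_px & r > (r_px - ring_w_px)
  phi <- matrix(NA_real_, dim_px, dim_px)
  imax <- matrix(0, dim_px, dim_px)
  phi[ring] <- wrap_axial(az[ring])     # radial axis
  imax[ring] <- i_max_levels[["ring"]]
  lobes <- list()
  if (n_lobes > 0) {
    offset <- stats::runif(1, 0, 360)
    for (k in seq_len(n_lobes)) {
      lobe_az <- offset + 360 * (k - 1) / n_lobes
      cx <- ctr + 0.5 * r_px * cos(deg2rad(lobe_az))
      cy <- ctr + 0.5 * r_px * sin(deg2rad(lobe_az))
      msk <- sqrt((xy$x - cx)^2 + (xy$y - cy)^2) <= 0.3 * r_px
      msk <- msk & !ring
      axis <- wrap_axial(lobe_az)
      phi[msk] <- axis
      imax[msk] <- i_max_levels[["lobe"]]
      lobes[[k]] <- list(mask = matrix(msk, dim_px, dim_px), axis = axis)
    }
  }
  active <- imax > 0
  theta <- matrix(NA_real_, dim_px, dim_px)
  theta[active] <- if (theta_sd > 0)
    rnorm_trunc(sum(active), theta_mean, theta_sd, 0, 90)
  else theta_mean
  synthetic_scene(phi, theta, imax, "platelet", pixel_size_nm,
                  extra = list(centre = c(ctr, ctr), radius_px = r_px,
                               ring_mask = matrix(ring, dim_px, dim_px),
                               lobes = lobes))
}

#' Bead phantom: tangential in-plane dipoles on a circle
#'
#' A ring of pixels on the perimeter of a circle with theta = 90 and phi
#' tangent to the circle, mimicking a dye-coated microsphere whose
#' intensity at fixed alpha varies sinusoidally (period 180 degrees)
#' around the perimeter.
#'
#' @param radius_px circle radius, pixels (>= 5).
#' @param i_max peak intensity on the perimeter.
#' @param dim_px image size; default fits the circle.
#' @param pixel_size_nm pixel size.
#' @export
make_bead_phantom <- function(radius_px = 10, i_max = 1000, dim_px = NULL,
                              pixel_size_nm = 60) {
  if (radius_px < 5) stop("radius_px must be >= 5")
  if (is.null(dim_px)) dim_px <- 2L * ceiling(radius_px) + 7L
  ctr <- (dim_px + 1) / 2
  xy <- expand.grid(y = seq_len(dim_px), x = seq_len(dim_px))
  r <- sqrt((xy$x - ctr)^2 + (xy$y - ctr)^2)
  az <- rad2deg(atan2(xy$y - ctr, xy$x - ctr))
  perim <- abs(r - radius_px) <= 0.75
  phi <- matrix(NA_real_, dim_px, dim_px)
  theta <- matrix(NA_real_, dim_px, dim_px)
  imax <- matrix(0, dim_px, dim_px)
  phi[perim] <- wrap_axial(az[perim] + 90)   # tangent axis
  theta[perim] <- 90
  imax[perim] <- i_max
  synthetic_scene(phi, theta, imax, "bead-phantom", pixel_size_nm,
                  extra = list(centre = c(ctr, ctr),
                               perim_mask = matrix(perim, dim_px, dim_px),
                               azimuth = matrix(az, dim_px, dim_px)))
}

#' Camera/photon noise model
#'
#' @param shot apply Poisson shot noise on expected photon counts.
#' @param read_sd Gaussian read noise standard deviation, counts.
#' @param baseline camera baseline added to every frame, counts.
#' @param seed RNG seed; identical seeds give identical montages.
#' @export
noise_model <- function(shot = TRUE, read_sd = 0, baseline = 200,
                        seed = NULL) {
  structure(list(shot = shot, read_sd = read_sd, baseline = baseline,
                 seed = seed), class = "noise_model")
}

# expected intensity field of a scene at polarization alpha
scene_expected <- function(scene, alpha, b = 0.069) {
  phi <- scene$phi; theta <- scene$theta
  phi[is.na(phi)] <- 0; theta[is.na(theta)] <- 0
  forward_intensity(phi, theta, scene$i_max, alpha, b)
}

apply_noise <- function(expected, noise) {
  d <- dim(expected)
  v <- as.numeric(expected)
  if (noise$shot) v <- stats::rpois(length(v), pmax(v, 0))
  if (noise$read_sd > 0) v <- v + stats::rnorm(length(v), 0, noise$read_sd)
  matrix(v + noise$baseline, d[1], d[2])
}

#' Render a scene into a raw striped SIM montage
#'
#' Each frame is the scene's expected polarized intensity (forward model
#' at the frame's alpha) modulated by a sinusoidal stripe pattern whose
#' orientation equals alpha (the excitation field E is parallel to the
#' stripes), phase-stepped by 2*pi/phases, then noised and offset by the
#' camera baseline. Stripe parameters are irrelevant after phase
#' averaging but make the raw frames realistic.
#'
#' @param scene a `synthetic_scene`.
#' @param alphas [alpha_triplet()].
#' @param phases phase steps per orientation, 3 or 5.
#' @param stripe_period_px stripe period, pixels (>= 4). Default 8.
#' @param modulation stripe modulation depth m in [0, 1). Default 0.8.
#' @param noise a [noise_model()].
#' @param b unstacked fraction used by the forward model.
#' @param ambient_photons unpolarized ambient fluorescence added to the
#'   expected intensity of every pixel (photons; also striped).
#' @param timestamp_min timestamp carried into the montage.
#' @return a [sim_montage()] (orientation-major frame order).
#' @export
render_montage <- function(scene, alphas = alpha_triplet(), phases = 5,
                           stripe_period_px = 8, modulation = 0.8,
                           noise = noise_model(), b = 0.069,
                           ambient_photons = 0, timestamp_min = 0) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!phases %in% c(3L, 5L)) stop("phases must be 3 or 5")
  if (stripe_period_px < 4) stop("stripe period must be >= 4 px")
  if (!inherits(alphas, "alpha_triplet")) alphas <- do.call(alpha_triplet, as.list(alphas))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  d <- dim(scene$i_max)
  xy <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]))
  frames <- array(0, c(d[1], d[2], 3L * phases))
  for (o in 1:3) {
    a <- as.numeric(alphas)[o]
    expected <- scene_expected(scene, a, b) + ambient_photons
    # stripes run along alpha; wavevector is perpendicular to alpha
    u <- matrix(-xy$x * sin(deg2rad(a)) + xy$y * cos(deg2rad(a)), d[1], d[2])
    for (p in seq_len(phases)) {
      stripe <- 1 + modulation *
        cos(2 * pi * u / stripe_period_px + 2 * pi * (p - 1) / phases)
      frames[, , (o - 1L) * phases + p] <- apply_noise(expected * stripe, noise)
    }
  }
  sim_montage(frames, alphas, phases, camera_baseline = noise$baseline,
              pixel_size_nm = scene$pixel_size_nm,
              timestamp_min = timestamp_min)
}

# integer translation with zero fill
shift_matrix <- function(m, dy, dx, fill = 0) {
  d <- dim(m)
  out <- matrix(fill, d[1], d[2])
  sr <- intersect(seq_len(d[1]), seq_len(d[1]) + dy)
  sc <- intersect(seq_len(d[2]), seq_len(d[2]) + dx)
  if (length(sr) && length(sc)) out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

shift_scene <- function(scene, dy, dx) {
  scene$phi <- shift_matrix(scene$phi, dy, dx, NA_real_)
  scene$theta <- shift_matrix(scene$theta, dy, dx, NA_real_)
  scene$i_max <- shift_matrix(scene$i_max, dy, dx, 0)
  scene
}

#' Timelapse schedule for platelet attachment / spreading / detachment
#'
#' Ground-truth kinetic parameters for [render_timelapse()]:
#' the tension-area curve T(t) (saturating-exponential spread followed by
#' a sigmoidal retraction; see [model_tension_area()]) and the
#' alignment curve R(t) (asymptotic exponential approach; see
#' [model_alignment()]).
#'
#' @param T_max,t_attach,t_detach,tau_spread,tau_retract,T0 tension-area
#'   parameters (micrometres^2 / minutes). Defaults follow the median
#'   platelet kinetics scale: T_max 20 um^2, tau_spread 1.7 min,
#'   tau_retract 5 min, t_detach 20 min.
#' @param R0,R_max,tau_align alignment parameters; tau_align default
#'   5 min.
#' @param axis_deg common force axis approached during alignment.
#' @export
timelapse_schedule <- function(T_max = 20, t_attach = 6, t_detach = 20,
                               tau_spread = 1.7, tau_retract = 5, T0 = 0.2,
                               R0 = 0.2, R_max = 0.7, tau_align = 5,
                               axis_deg = 30) {
  structure(list(T_max = T_max, t_attach = t_attach, t_detach = t_detach,
                 tau_spread = tau_spread, tau_retract = tau_retract,
                 T0 = T0, R0 = R0, R_max = R_max, tau_align = tau_align,
                 axis_deg = axis_deg), class = "timelapse_schedule")
}

#' Render a synthetic timelapse of montages
#'
#' Emulates a platelet attaching, spreading, aligning its traction and
#' detaching: at each timepoint the active tension footprint is a
#' centred disk whose area follows the schedule's T(t); per-pixel phi is
#' a mixture of a common axis (fraction R(t)) and fixed isotropic draws,
#' so the measured alignment parameter tracks R(t) in expectation.
#' Global intensity decays as exp(-t / bleach_tau) and the whole scene
#' drifts by `drift_per_frame` pixels per frame.
#'
#' @param schedule a [timelapse_schedule()].
#' @param interval_min frame interval, minutes. Default 2.
#' @param duration_min total duration, minutes. Default 82.
#' @param dim_px image size (must hold the T_max footprint at the
#'   chosen pixel size).
#' @param pixel_size_nm synthetic pixel size; coarser pixels keep small
#'   test frames while holding realistic areas.
#' @param i_max peak intensity, photons, before bleaching.
#' @param theta_deg tilt angle of the synthetic forces.
#' @param ambient_photons unpolarized ambient fluorescence level at
#'   t = 0, photons; bleaches with the same time constant. Gives the
#'   background region a signal whose decay the bleach correction can
#'   fit (and makes no frame featureless).
#' @param bleach_tau photobleaching time constant, minutes (Inf = none).
#' @param drift_per_frame integer (dy, dx) drift per frame, pixels.
#' @param noise a [noise_model()]; its seed controls all randomness.
#' @param alphas,phases,stripe_period_px,modulation passed to
#'   [render_montage()].
#' @return list with `montages` (list of [sim_montage()]),
#'   `time_min`, `truth` (per-frame T, R, shift and the schedule).
#' @export
render_timelapse <- function(schedule = timelapse_schedule(),
                             interval_min = 2, duration_min = 82,
                             dim_px = 96, pixel_size_nm = 60,
                             i_max = 1000, theta_deg = 90,
                             ambient_photons = 50, bleach_tau = Inf,
                             drift_per_frame = c(0, 0),
                             noise = noise_model(),
                             alphas = alpha_triplet(), phases = 5,
                             stripe_period_px = 8, modulation = 0.8) {
  stopifnot(inherits(schedule, "timelapse_schedule"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  tt <- seq(0, duration_min, by = interval_min)
  px_um2 <- (pixel_size_nm / 1000)^2
  ctr <- (dim_px + 1) / 2
  xy <- expand.grid(y = seq_len(dim_px), x = seq_len(dim_px))
  r <- matrix(sqrt((xy$x - ctr)^2 + (xy$y - ctr)^2), dim_px, dim_px)
  ord <- order(r)                       # grow the footprint from the centre
  # fixed per-pixel isotropic angles: the same pixel keeps its angle
  # across frames, so only the aligned fraction evolves
  phi_iso <- matrix(stats::runif(dim_px^2, 0, 180), dim_px, dim_px)
  T_true <- model_tension_area(tt, schedule$T_max, schedule$t_attach,
                               schedule$t_detach, schedule$tau_spread,
                               schedule$tau_retract, 0)
  R_true <- model_alignment(tt, schedule$R0, schedule$R_max,
                            schedule$tau_align, schedule$t_attach)
  montages <- vector("list", length(tt))
  shifts <- matrix(0L, length(tt), 2)
  for (k in seq_along(tt)) {
    n_act <- min(round(T_true[k] / px_um2), dim_px^2)
    phi <- matrix(NA_real_, dim_px, dim_px)
    theta <- matrix(NA_real_, dim_px, dim_px)
    imax <- matrix(0, dim_px, dim_px)
    if (n_act > 0) {
      act <- ord[seq_len(n_act)]
      q <- min(max(R_true[k], 0), 1)
      n_ali <- round(q * n_act)
      aligned <- act[seq_len(n_ali)]
      phi[act] <- phi_iso[act]
      if (n_ali > 0) phi[aligned] <- schedule$axis_deg
      theta[act] <- theta_deg
      imax[act] <- i_max * exp(-tt[k] / bleach_tau)
    }
    scene <- synthetic_scene(phi, theta, imax, "platelet", pixel_size_nm)
    sh <- as.integer(round((k - 1) * drift_per_frame))
    shifts[k, ] <- sh
    if (any(sh != 0)) scene <- shift_scene(scene, sh[1], sh[2])
    frame_noise <- noise
    frame_noise$seed <- NULL            # keep one RNG stream for the run
    montages[[k]] <- render_montage(
      scene, alphas, phases, stripe_period_px, modulation, frame_noise,
      ambient_photons = ambient_photons * exp(-tt[k] / bleach_tau),
      timestamp_min = tt[k])
  }
  list(montages = montages, time_min = tt,
       truth = list(T = T_true, R = R_true, shifts = shifts,
                    schedule = schedule, bleach_tau = bleach_tau,
                    drift_per_frame = drift_per_frame))
}
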