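#' Raw SIM acquisition montage
#'
#' One acquisition: 3 stripe orientations x P phase steps (P = 5 for
#' "3D-SIM", 3 for "2D-SIM"), stored as a stack of frames plus camera
#' metadata. Frame order is orientation-major by default (all phases of
#' orientation 1, then orientation 2, ...); vendor exports that interleave
#' phases can be declared with `layout = "phase-major"`.
#'
#' @param frames numeric array `[rows, cols, 3 * phases]`.
#' @param alphas [alpha_triplet()] of stripe/polarization orientations.
#' @param phases phase steps per orientation (3 or 5).
#' @param camera_baseline CCD baseline, counts. Default 200.
#' @param pixel_size_nm pixel size. Default 60.
#' @param layout "orientation-major" or "phase-major".
#' @param timestamp_min acquisition time, minutes (timelapse use).
#' @return a `sim_montage` object.
#' @export
sim_montage <- function(frames, alphas = alpha_triplet(), phases = 5,
                        camera_baseline = 200, pixel_size_nm = 60,
                        layout = c("orientation-major", "phase-major"),
                        timestamp_min = 0) {
  layout <- match.arg(layout)
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[3] != 3L * phases)
    stop("frame count ", dim(frames)[3], " != 3 * phases (", 3 * phases, ")")
  if (!inherits(alphas, "alpha_triplet")) alphas <- do.call(alpha_triplet, as.list(alphas))
  structure(list(frames = frames, alphas = alphas, phases = phases,
                 camera_baseline = camera_baseline,
                 pixel_size_nm = pixel_size_nm, layout = layout,
                 timestamp_min = timestamp_min),
            class = "sim_montage")
}

# frame index of (orientation o, phase p) under the montage's layout
frame_index <- function(m, o, p) {
  if (m$layout == "orientation-major") (o - 1L) * m$phases + p
  else (p - 1L) * 3L + o
}

#' Disk-kernel mean smoothing (rolling-ball style)
#'
#' Grayscale smoothing with a flat circular kernel of the given pixel
#' radius, edge-replicated borders. Used to suppress stripe remnants and
#' shot noise when building illumination profiles.
#'
#' @param img numeric matrix.
#' @param radius kernel radius, pixels.
#' @return smoothed matrix, same dimensions.
#' @export
smooth_disk <- function(img, radius = 3) {
  if (radius <= 0) return(img)
  r <- as.integer(ceiling(radius))
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  nr <- nrow(img); nc <- ncol(img)
  # edge-replicated padding
  ridx <- pmin(pmax(seq_len(nr + 2L * r) - r, 1L), nr)
  cidx <- pmin(pmax(seq_len(nc + 2L * r) - r, 1L), nc)
  pad <- img[ridx, cidx, drop = FALSE]
  acc <- matrix(0, nr, nc)
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    acc <- acc + pad[(r + 1L + dy):(r + nr + dy), (r + 1L + dx):(r + nc + dx)]
  }
  acc / nrow(offs)
}

#' Illumination profile from uniform-sample montages
#'
#' Flat-field correction montage built from acquisitions of a uniform
#' fluorescent slide (or a fully opened probe surface): baseline-subtract
#' each montage, smooth every frame with a disk kernel, average the
#' montages, and normalize so the mean over the whole montage is 1.
#'
#' @param montages list of [sim_montage()] objects sharing shape/layout
#'   (at least six acquisitions recommended; fewer triggers a warning).
#' @param ball_radius smoothing radius in pixels. Default 3.
#' @return an `illumination_profile`: the normalized montage array plus
#'   layout metadata.
#' @export
build_illumination_profile <- function(montages, ball_radius = 3) {
  if (inherits(montages, "sim_montage")) montages <- list(montages)
  stopifnot(length(montages) >= 1L)
  if (length(montages) < 6L)
    warning("illumination profile built from ", length(montages),
            " montage(s); at least 6 recommended")
  d <- dim(montages[[1]]$frames)
  acc <- array(0, d)
  for (m in montages) {
    if (!identical(dim(m$frames), d)) stop("montages must share dimensions")
    sub <- m$frames - m$camera_baseline
    for (f in seq_len(d[3])) sub[, , f] <- smooth_disk(sub[, , f], ball_radius)
    acc <- acc + sub
  }
  acc <- acc / length(montages)
  if (any(acc <= 0))
    stop("illumination profile contains nonpositive smoothed values; ",
         "profile unusable")
  acc <- acc / mean(acc)
  structure(list(frames = acc, layout = montages[[1]]$layout,
                 phases = montages[[1]]$phases, ball_radius = ball_radius),
            class = "illumination_profile")
}

#' Correct a raw montage
#'
#' Applies the standard-resolution preprocessing recipe, in order:
#' subtract the camera baseline; divide by the illumination profile;
#' subtract the 1st percentile of the whole montage (skipped in timelapse
#' mode, where frame-to-frame intensity must stay comparable); clamp
#' negative values to zero.
#'
#' @param m a [sim_montage()].
#' @param profile an `illumination_profile` (or NULL for a unit profile).
#' @param subtract_percentile subtract the montage 1st percentile
#'   (set FALSE for timelapse processing).
#' @param percentile percentile used for the offset, default 0.01.
#' @return a corrected `sim_montage` (baseline reset to 0).
#' @export
correct_montage <- function(m, profile = NULL, subtract_percentile = TRUE,
                            percentile = 0.01) {
  stopifnot(inherits(m, "sim_montage"))
  fr <- m$frames - m$camera_baseline
  if (!is.null(profile)) {
    if (!identical(dim(profile$frames), dim(fr)))
      stop("profile shape does not match montage")
    if (any(profile$frames <= 0)) stop("nonpositive illumination profile")
    fr <- fr / profile$frames
  }
  if (subtract_percentile)
    fr <- fr - stats::quantile(fr, percentile, names = FALSE)
  fr[fr < 0] <- 0
  out <- m
  out$frames <- fr
  out$camera_baseline <- 0
  out
}

#' Phase-average a corrected montage into a polarization triplet
#'
#' Averages the P phase-shifted frames of each stripe orientation. The
#' phase steps of 2*pi/P cancel the stripe modulation exactly, leaving
#' one stripe-free image per polarization angle alpha.
#'
#' @param m a (corrected) [sim_montage()].
#' @return a [polarization_triplet()] with alpha labels from the montage.
#' @export
phase_average <- function(m) {
  stopifnot(inherits(m, "sim_montage"))
  d <- dim(m$frames)
  if (d[3] %% 3L != 0L) stop("frame count not divisible by 3")
  images <- lapply(1:3, function(o) {
    idx <- frame_index(m, o, seq_len(m$phases))
    if (length(idx) == 1L) m$frames[, , idx]
    else rowMeans(m$frames[, , idx, drop = FALSE], dims = 2)
  })
  polarization_triplet(images, m$alphas, m$pixel_size_nm)
}

#' One-call preprocessing: raw montage to orientation map
#'
#' Convenience wrapper chaining [correct_montage()], [phase_average()]
#' and [fit_image_triplet()].
#'
#' @inheritParams correct_montage
#' @inheritParams fit_image_triplet
#' @return an `orientation_map`.
#' @export
process_montage <- function(m, profile = NULL, subtract_percentile = TRUE,
                            params = dipole_params(), mask_quantile = 0.60) {
  fit_image_triplet(
    phase_average(correct_montage(m, profile, subtract_percentile)),
    params = params, mask_quantile = mask_quantile)
}
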