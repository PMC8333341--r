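#' Axial (180-degree-periodic) angle helpers
#'
#' In-plane force angles phi are axial data: phi and phi + 180 denote the
#' same measurement. All phi arithmetic in this package therefore runs on
#' doubled angles (the standard device for axial circular statistics).
#'
#' @name axial
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to the axial fundamental domain [0, 180)
#' @param phi angles in degrees.
#' @return angles reduced modulo 180 into [0, 180).
#' @export
wrap_axial <- function(phi) {
  out <- phi %% 180
  # guard against 180 - eps rounding back up to exactly 180
  out[out >= 180] <- 0
  out
}

#' Signed axial difference a - b in (-90, 90]
#'
#' @param a,b angles in degrees (axial convention).
#' @return signed differences; magnitude never exceeds 90 degrees.
#' @export
axial_diff <- function(a, b) {
  d <- (a - b) %% 180
  d[d > 90] <- d[d > 90] - 180
  d
}

#' Absolute axial distance between two angles (<= 90 degrees)
#' @inheritParams axial_diff
#' @export
axial_dist <- function(a, b) abs(axial_diff(a, b))

#' Axial circular mean of a set of phi angles
#'
#' Computed as half the argument of the mean resultant of the doubled
#' angles, wrapped back to [0, 180). The arithmetic mean is biased near the
#' wrap point; this estimator is not.
#'
#' @param phi angles in degrees.
#' @param w optional non-negative weights.
#' @return mean angle in [0, 180); NA if the resultant vanishes.
#' @export
axial_mean <- function(phi, w = NULL) {
  phi <- phi[is.finite(phi)]
  if (length(phi) == 0L) return(NA_real_)
  z <- exp(2i * deg2rad(phi))
  m <- if (is.null(w)) mean(z) else sum(w * z) / sum(w)
  if (Mod(m) < .Machine$double.eps) return(NA_real_)
  wrap_axial(rad2deg(Arg(m)) / 2)
}
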