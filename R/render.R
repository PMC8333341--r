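#' Orientation-map display
#'
#' Two display styles for orientation maps: a per-pixel colormap (hue =
#' phi on a 180-degree circular HSV wheel, or theta on a sequential jet
#' scale, with pixel brightness scaled to Imax between percentile
#' bounds) and a dipole plot (a short line segment per pixel, oriented
#' at phi, length proportional to Imax, colored by theta, on a gray
#' background).
#'
#' @name polforce-render
#' @keywords internal
NULL

#' Rendering options
#'
#' @param style "colormap-phi", "colormap-theta" or "dipole".
#' @param mask_quantile Imax quantile below which pixels are not drawn.
#'   Default 0.60.
#' @param brightness_lo,brightness_hi Imax percentile bounds mapped to
#'   minimum/maximum brightness. Defaults 0.35 and 0.99.
#' @param dipole_stride draw a dipole every `stride` pixels (1 =
#'   per-pixel). Default 2.
#' @param dipole_len_px maximum dipole half-length, pixels.
#' @param wheel_rotation rotate the phi color wheel, degrees.
#' @export
render_spec <- function(style = c("colormap-phi", "colormap-theta", "dipole"),
                        mask_quantile = 0.60, brightness_lo = 0.35,
                        brightness_hi = 0.99, dipole_stride = 2,
                        dipole_len_px = 3, wheel_rotation = 0) {
  style <- match.arg(style)
  stopifnot(brightness_lo >= 0, brightness_hi <= 1,
            brightness_lo < brightness_hi,
            mask_quantile >= 0, mask_quantile <= 1)
  structure(list(style = style, mask_quantile = mask_quantile,
                 brightness_lo = brightness_lo,
                 brightness_hi = brightness_hi,
                 dipole_stride = dipole_stride,
                 dipole_len_px = dipole_len_px,
                 wheel_rotation = wheel_rotation),
            class = "render_spec")
}

# jet-style colormap: value in [0, 1] -> RGB matrix (n x 3)
jet_rgb <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  cbind(r, g, b)
}

# brightness channel: Imax clipped/scaled between the percentile bounds
imax_brightness <- function(i_max, spec) {
  qs <- stats::quantile(i_max, c(spec$brightness_lo, spec$brightness_hi),
                        na.rm = TRUE, names = FALSE)
  if (qs[2] <= qs[1]) {
    # degenerate (constant) Imax: full brightness at/above the bound
    out <- i_max
    out[] <- as.numeric(i_max >= qs[1])
    return(out)
  }
  pmin(pmax((i_max - qs[1]) / (qs[2] - qs[1]), 0), 1)
}

#' Colormap rendering of an orientation map
#'
#' @param map an `orientation_map`.
#' @param spec a [render_spec()] with style "colormap-phi" (circular
#'   HSV hue, exactly 180-degree periodic) or "colormap-theta" (jet).
#' @return an `rows x cols x 3` RGB array in [0, 1].
#' @export
render_colormap <- function(map, spec = render_spec("colormap-phi")) {
  stopifnot(inherits(map, "orientation_map"))
  d <- dim(map$phi)
  val <- imax_brightness(map$i_max, spec)
  shown <- map$valid &
    map$i_max >= stats::quantile(map$i_max, spec$mask_quantile,
                                 na.rm = TRUE, names = FALSE)
  out <- array(0, c(d, 3))
  idx <- which(shown)
  if (length(idx)) {
    if (spec$style == "colormap-theta") {
      rgb <- jet_rgb(map$theta[idx] / 90)
    } else {
      hue <- (wrap_axial(map$phi[idx] + spec$wheel_rotation)) / 180
      rgb <- t(grDevices::col2rgb(grDevices::hsv(hue, 1, 1))) / 255
    }
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[idx] <- rgb[, ch] * val[idx]
      out[, , ch] <- plane
    }
  }
  out
}

#' Dipole rendering of an orientation map
#'
#' One line segment per (strided) supra-threshold pixel, oriented at
#' phi, with half-length proportional to Imax and color encoding theta,
#' rasterized onto a gray background.
#'
#' @param map an `orientation_map`.
#' @param spec a [render_spec()] (style "dipole").
#' @return list with `raster` (RGB array) and `segments` (data frame:
#'   row, col, phi, theta, i_max, half_len_px).
#' @export
render_dipole_map <- function(map, spec = render_spec("dipole")) {
  stopifnot(inherits(map, "orientation_map"))
  d <- dim(map$phi)
  thr <- stats::quantile(map$i_max, spec$mask_quantile, na.rm = TRUE,
                         names = FALSE)
  shown <- map$valid & map$i_max >= thr
  rows <- seq(1, d[1], by = spec$dipole_stride)
  cols <- seq(1, d[2], by = spec$dipole_stride)
  keep <- which(shown[rows, cols, drop = FALSE], arr.ind = TRUE)
  raster <- array(0.5, c(d, 3))  # gray background
  if (nrow(keep) == 0L) {
    warning("all pixels masked; empty dipole render")
    return(list(raster = raster,
                segments = data.frame(row = numeric(0), col = numeric(0),
                                      phi = numeric(0), theta = numeric(0),
                                      i_max = numeric(0),
                                      half_len_px = numeric(0))))
  }
  rr <- rows[keep[, 1]]; cc <- cols[keep[, 2]]
  ii <- cbind(rr, cc)
  imax <- map$i_max[ii]
  half <- spec$dipole_len_px * pmin(imax / max(imax), 1)
  segs <- data.frame(row = rr, col = cc, phi = map$phi[ii],
                     theta = map$theta[ii], i_max = imax,
                     half_len_px = half)
  col_rgb <- jet_rgb(segs$theta / 90)
  for (s in seq_len(nrow(segs))) {
    n_pts <- max(2L * ceiling(segs$half_len_px[s]) + 1L, 3L)
    tseq <- seq(-segs$half_len_px[s], segs$half_len_px[s],
                length.out = n_pts)
    py <- round(segs$row[s] + tseq * sin(deg2rad(segs$phi[s])))
    px <- round(segs$col[s] + tseq * cos(deg2rad(segs$phi[s])))
    ok <- py >= 1 & py <= d[1] & px >= 1 & px <= d[2]
    for (ch in 1:3) {
      plane <- raster[, , ch]
      plane[cbind(py[ok], px[ok])] <- col_rgb[s, ch]
      raster[, , ch] <- plane
    }
  }
  list(raster = raster, segments = segs)
}

#' Write an RGB array to PNG
#'
#' @param rgb `rows x cols x 3` array in [0, 1].
#' @param path output file.
#' @param scale integer pixel magnification.
#' @export
save_render_png <- function(rgb, path, scale = 4) {
  d <- dim(rgb)
  grDevices::png(path, width = d[2] * scale, height = d[1] * scale)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::rasterImage(rgb, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
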