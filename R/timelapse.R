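#' Platelet traction dynamics from timelapse acquisitions
#'
#' Per-cell time series of two scalars summarize a platelet's mechanical
#' life cycle: the tension area T(t) (surface area of supra-threshold
#' tension signal, um^2) and the alignment parameter R(t) (one minus the
#' circular variance of the in-plane force angles under the cell, on
#' doubled angles). T(t) is fit to a spread-then-retract curve,
#'
#'   T = T_max u(t - t_attach) [ (1 - exp(-(t - t_attach)/tau_spread))
#'        - 1 / (1 + exp(-(t - t_attach - t_detach)/tau_retract)) ] + T0
#'
#' by simulated annealing plus local refinement, and R(t) on the
#' attachment window to an asymptotic approach
#'
#'   R = R_max - (R_max - R0) exp(-(t - t_attach)/tau_align).
#'
#' @name polforce-timelapse
#' @keywords internal
NULL

#' Tension-area kinetic model
#'
#' @param t time, minutes.
#' @param T_max maximum tension area, um^2.
#' @param t_attach attachment time, minutes.
#' @param t_detach duration from attachment to detachment, minutes.
#' @param tau_spread,tau_retract spreading / retraction time constants.
#' @param T0 basal tension area (noise floor), um^2.
#' @return tension area at `t`; tends back to `T0` as t grows.
#' @export
model_tension_area <- function(t, T_max, t_attach, t_detach,
                               tau_spread, tau_retract, T0 = 0) {
  dt <- pmax(t - t_attach, 0)          # u(t - t_attach) gate
  u <- as.numeric(t >= t_attach)
  T_max * u * ((1 - exp(-dt / tau_spread)) -
                 1 / (1 + exp(pmin((t_detach - dt) / tau_retract, 700)))) + T0
}

#' Alignment kinetic model
#'
#' @param t time, minutes.
#' @param R0,R_max initial and plateau alignment parameters.
#' @param tau_align alignment time constant, minutes.
#' @param t_attach attachment time (fixed from the tension-area fit).
#' @export
model_alignment <- function(t, R0, R_max, tau_align, t_attach = 0) {
  R_max - (R_max - R0) * exp(-(t - t_attach) / tau_align)
}

#' Alignment parameter of a set of in-plane angles
#'
#' R = |mean of exp(2 i phi)|, the mean resultant length on doubled
#' angles, which equals one minus the circular variance of the axial
#' angles: 1 for perfect alignment along one axis, 0 for an isotropic
#' set.
#'
#' @param phis angles in degrees (NAs dropped).
#' @param weights optional non-negative weights (e.g., Imax).
#' @return R in [0, 1].
#' @export
alignment_parameter <- function(phis, weights = NULL) {
  keep <- is.finite(phis)
  if (!is.null(weights)) keep <- keep & is.finite(weights)
  phis <- phis[keep]
  if (length(phis) == 0L) stop("no valid phi angles")
  z <- exp(2i * deg2rad(phis))
  if (is.null(weights)) Mod(mean(z))
  else {
    w <- weights[keep]
    Mod(sum(w * z) / sum(w))
  }
}

#' Tension area of a frame
#'
#' Number of supra-threshold pixels times the pixel area. The default
#' threshold rule is background mean + k * background sd (k = 3); pass
#' `threshold` to override it explicitly.
#'
#' @param x an `orientation_map` or a numeric intensity matrix (Imax).
#' @param threshold explicit intensity threshold (takes precedence).
#' @param background_mask logical matrix of cell-free pixels used by the
#'   default rule.
#' @param k threshold stringency, default 3.
#' @param pixel_size_nm pixel size (taken from the map if available).
#' @return tension area, um^2.
#' @export
tension_area <- function(x, threshold = NULL, background_mask = NULL,
                         k = 3, pixel_size_nm = NULL) {
  if (inherits(x, "orientation_map")) {
    if (is.null(pixel_size_nm)) pixel_size_nm <- x$pixel_size_nm
    img <- x$i_max
  } else img <- x
  if (is.null(pixel_size_nm)) pixel_size_nm <- 60
  if (is.null(threshold)) {
    if (is.null(background_mask))
      stop("need either an explicit threshold or a background_mask")
    bg <- img[background_mask]
    threshold <- mean(bg) + k * stats::sd(bg)
  }
  sum(img > threshold, na.rm = TRUE) * (pixel_size_nm / 1000)^2
}

#' Per-platelet track
#'
#' @param time_min time axis, minutes (uniform sampling).
#' @param T tension area series, um^2.
#' @param R alignment parameter series in [0, 1] (NA allowed where no
#'   tension pixels exist).
#' @return a `platelet_track` data frame.
#' @export
platelet_track <- function(time_min, T, R = rep(NA_real_, length(time_min))) {
  stopifnot(length(T) == length(time_min), length(R) == length(time_min))
  if (any(T < 0, na.rm = TRUE)) stop("tension area must be >= 0")
  if (any(R < -1e-9 | R > 1 + 1e-9, na.rm = TRUE)) stop("R must lie in [0, 1]")
  structure(data.frame(time_min = time_min, T = T, R = R),
            class = c("platelet_track", "data.frame"))
}

## ---- drift correction -----------------------------------------------------

# translation of img relative to ref by phase cross-correlation,
# subpixel-refined with a parabolic fit around the integer peak.
# The normalized correlation peak is ~1 for a clean translation and
# ~0.1 for unrelated content; below `min_confidence` the estimate is
# meaningless and a zero shift is the safe fallback.
phase_corr_shift <- function(ref, img, min_confidence = 0.15) {
  if (stats::sd(ref) == 0 || stats::sd(img) == 0) {
    warning("flat frame: registration skipped, zero shift assumed")
    return(c(0, 0))
  }
  F1 <- stats::fft(ref)
  F2 <- stats::fft(img)
  Rn <- F1 * Conj(F2)
  mag <- Mod(Rn)
  mag[mag < .Machine$double.eps] <- 1
  cc <- Re(stats::fft(Rn / mag, inverse = TRUE))
  if (max(cc) / length(cc) < min_confidence) {
    warning("low-confidence registration (featureless or unrelated ",
            "frames); zero shift assumed")
    return(c(0, 0))
  }
  d <- dim(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  refine <- function(i, n, along_row) {
    idx <- function(j) ((j - 1) %% n) + 1
    if (along_row) {
      y0 <- cc[idx(i - 1), pk[2]]; y1 <- cc[idx(i), pk[2]]; y2 <- cc[idx(i + 1), pk[2]]
    } else {
      y0 <- cc[pk[1], idx(i - 1)]; y1 <- cc[pk[1], idx(i)]; y2 <- cc[pk[1], idx(i + 1)]
    }
    den <- y0 - 2 * y1 + y2
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / den
  }
  sh <- c(pk[1] - 1 + refine(pk[1], d[1], TRUE),
          pk[2] - 1 + refine(pk[2], d[2], FALSE))
  # unwrap: shifts beyond half the frame are negative
  sh <- ifelse(sh > dim(cc) / 2, sh - dim(cc), sh)
  -sh  # sign convention: img[y, x] = ref[y - dy, x - dx] gives c(dy, dx)
}

#' Drift-correct a timelapse stack
#'
#' Estimates the translation between successive frames by phase
#' cross-correlation and removes the cumulative drift, aligning every
#' frame to the first. Works on a list of matrices or of
#' [sim_montage()] objects (montages are registered on their frame mean
#' and every frame is shifted).
#'
#' @param stack list of numeric matrices or `sim_montage`s (>= 1).
#' @return list with `stack` (corrected, same type) and `shifts`
#'   (n x 2 matrix of cumulative (dy, dx) pixel shifts).
#' @export
drift_correct <- function(stack) {
  stopifnot(is.list(stack), length(stack) >= 1L)
  is_montage <- inherits(stack[[1]], "sim_montage")
  reg_img <- function(x) if (is_montage) rowMeans(x$frames, dims = 2) else x
  n <- length(stack)
  shifts <- matrix(0, n, 2)
  if (n >= 2L) for (k in 2:n) {
    shifts[k, ] <- shifts[k - 1, ] +
      phase_corr_shift(reg_img(stack[[k - 1]]), reg_img(stack[[k]]))
  }
  out <- stack
  for (k in seq_len(n)) {
    sh <- round(shifts[k, ])
    if (all(sh == 0)) next
    if (is_montage) {
      for (f in seq_len(dim(out[[k]]$frames)[3]))
        out[[k]]$frames[, , f] <-
          shift_matrix(out[[k]]$frames[, , f], -sh[1], -sh[2])
    } else out[[k]] <- shift_matrix(out[[k]], -sh[1], -sh[2])
  }
  list(stack = out, shifts = shifts)
}

## ---- photobleach correction ----------------------------------------------

#' Photobleach-correct a timelapse stack
#'
#' Fits the mean intensity of a cell-free background region to an
#' exponential decay a * exp(-t / tau) (+ optional offset) and divides
#' every frame by the fitted curve normalized to t = 0. A non-decaying
#' background yields tau = Inf and a no-op correction with a warning.
#'
#' @param stack list of matrices or [sim_montage()]s.
#' @param background_mask logical matrix selecting cell-free pixels.
#' @param time_min time of each frame, minutes.
#' @param offset include an additive offset in the decay fit.
#' @return list with `stack` (normalized), `tau` (minutes), `a`,
#'   `offset`, and `factor` (per-frame correction divisor).
#' @export
photobleach_correct <- function(stack, background_mask, time_min,
                                offset = FALSE) {
  stopifnot(length(stack) == length(time_min))
  is_montage <- inherits(stack[[1]], "sim_montage")
  bg_mean <- vapply(stack, function(x) {
    img <- if (is_montage) rowMeans(x$frames, dims = 2) else x
    mean(img[background_mask])
  }, numeric(1))
  t <- time_min - time_min[1]
  slope <- stats::coef(stats::lm(bg_mean ~ t))[2]
  fit_ok <- FALSE
  a <- bg_mean[1]; tau <- Inf; d0 <- 0
  if (is.finite(slope) && slope < 0 && all(bg_mean > 0)) {
    # log-linear start, then nonlinear refinement
    st <- stats::coef(stats::lm(log(bg_mean) ~ t))
    start <- list(a = exp(st[1]), tau = max(-1 / st[2], 1e-3))
    fml <- if (offset) bg_mean ~ a * exp(-t / tau) + d else
      bg_mean ~ a * exp(-t / tau)
    if (offset) start$d <- 0
    fit <- tryCatch(stats::nls(fml, start = start,
                               control = stats::nls.control(warnOnly = TRUE)),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      if (cf[["tau"]] > 0) {
        a <- cf[["a"]]; tau <- cf[["tau"]]
        d0 <- if (offset) cf[["d"]] else 0
        fit_ok <- TRUE
      }
    }
  }
  if (!fit_ok) {
    warning("background does not decay; photobleach correction is a no-op")
    factor <- rep(1, length(stack))
  } else {
    curve <- a * exp(-t / tau) + d0
    factor <- curve / curve[1]
  }
  out <- stack
  for (k in seq_along(out)) {
    if (is_montage) out[[k]]$frames <- out[[k]]$frames / factor[k]
    else out[[k]] <- out[[k]] / factor[k]
  }
  list(stack = out, tau = tau, a = a, offset = d0, factor = factor)
}

## ---- kinetic fits ---------------------------------------------------------

sa_minimize <- function(fn, lower, upper, start, n_iter = 1500,
                        n_restarts = 5, cooling = 0.995) {
  np <- length(lower)
  scale <- 0.1 * (upper - lower)
  best_p <- start
  best_f <- fn(start)
  for (rs in seq_len(n_restarts)) {
    p <- if (rs == 1L) start else stats::runif(np, lower, upper)
    f <- fn(p)
    temp <- max(f, .Machine$double.eps)
    for (it in seq_len(n_iter)) {
      cand <- p + stats::rnorm(np, 0, scale)
      cand <- pmin(pmax(cand, lower), upper)
      fc <- fn(cand)
      if (fc < f || stats::runif(1) < exp((f - fc) / temp)) {
        p <- cand; f <- fc
        if (f < best_f) { best_f <- f; best_p <- p }
      }
      temp <- temp * cooling
    }
  }
  ref <- tryCatch(
    stats::optim(best_p, fn, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 500)),
    error = function(e) list(par = best_p, value = best_f))
  if (ref$value <= best_f) list(par = ref$par, value = ref$value)
  else list(par = best_p, value = best_f)
}

#' Fit the tension-area kinetic model to a track
#'
#' Minimizes the sum of squared residuals of [model_tension_area()] by
#' simulated annealing (exponential cooling, 5 restarts, bounded
#' parameters) followed by L-BFGS-B refinement. Deterministic for a
#' given seed.
#'
#' @param track a [platelet_track()] with >= 10 timepoints.
#' @param seed RNG seed for the annealing schedule.
#' @param flag_rmse_frac relative RMSE above which the fit is flagged.
#' @return a `spread_fit` list: T_max, t_attach, t_detach, tau_spread,
#'   tau_retract, T0 (um^2 / minutes), `rmse`, and logical `flagged`.
#' @export
fit_spreading <- function(track, seed = 1, flag_rmse_frac = 0.25) {
  stopifnot(nrow(track) >= 10L)
  if (!is.null(seed)) set.seed(seed)
  t <- track$time_min; Tv <- track$T
  rngT <- max(Tv) - min(Tv)
  if (max(Tv) <= 0 || rngT <= .Machine$double.eps) {
    return(structure(list(T_max = 0, t_attach = NA_real_,
                          t_detach = NA_real_, tau_spread = NA_real_,
                          tau_retract = NA_real_, T0 = stats::median(Tv),
                          rmse = 0, flagged = TRUE, degenerate = TRUE),
                     class = "spread_fit"))
  }
  dt <- if (length(t) > 1) t[2] - t[1] else 1
  dur <- diff(range(t))
  # heuristic initialization
  half <- min(Tv) + 0.5 * rngT
  above <- which(Tv > half)
  ta0 <- t[max(min(above) - 1L, 1L)]
  td0 <- max(t[max(above)] - ta0, dt)
  p0 <- c(rngT, ta0, td0, 2, 5, max(min(Tv), 0))
  lower <- c(0, min(t) - dt, dt / 2, 0.1, 0.1, 0)
  upper <- c(2 * max(Tv), max(t) + dt, 1.5 * dur + dt, 60, 60, max(Tv))
  p0 <- pmin(pmax(p0, lower), upper)
  fn <- function(p) {
    sum((model_tension_area(t, p[1], p[2], p[3], p[4], p[5], p[6]) - Tv)^2)
  }
  sol <- sa_minimize(fn, lower, upper, p0)
  p <- sol$par
  rmse <- sqrt(sol$value / length(t))
  structure(list(T_max = p[1], t_attach = p[2], t_detach = p[3],
                 tau_spread = p[4], tau_retract = p[5], T0 = p[6],
                 rmse = rmse, flagged = rmse > flag_rmse_frac * p[1],
                 degenerate = FALSE),
            class = "spread_fit")
}

#' Fit the alignment kinetic model on the attachment window
#'
#' Restricts the track to t in [t_attach, t_attach + t_detach]
#' (t_attach is held fixed from the tension-area fit), classifies the
#' trend (rank correlation of R vs t at alpha = 0.05: "increasing",
#' "decreasing" or "none"), and fits R0, R_max and tau_align by bounded
#' least squares.
#'
#' @param track a [platelet_track()].
#' @param t_attach,t_detach window from [fit_spreading()].
#' @param alpha significance level of the trend test.
#' @return an `align_fit` list: R0, R_max, tau_align, delta_R, `trend`,
#'   `p_trend`, `n_window`.
#' @export
fit_alignment <- function(track, t_attach, t_detach, alpha = 0.05) {
  win <- track$time_min >= t_attach &
    track$time_min <= t_attach + t_detach & is.finite(track$R)
  t <- track$time_min[win]; R <- track$R[win]
  if (length(t) < 3L)
    return(structure(list(R0 = NA_real_, R_max = NA_real_,
                          tau_align = NA_real_, delta_R = NA_real_,
                          trend = "unclassifiable", p_trend = NA_real_,
                          n_window = length(t)), class = "align_fit"))
  ct <- suppressWarnings(stats::cor.test(t, R, method = "spearman"))
  trend <- if (is.na(ct$p.value) || ct$p.value >= alpha) "none"
    else if (ct$estimate > 0) "increasing" else "decreasing"
  fn <- function(p) sum((model_alignment(t, p[1], p[2], p[3], t_attach) - R)^2)
  lower <- c(0, 0, 0.1); upper <- c(1, 1, 60)
  p0 <- c(max(min(R[1], 1), 0), max(min(R[length(R)], 1), 0), 5)
  sol <- tryCatch(
    stats::optim(p0, fn, method = "L-BFGS-B", lower = lower, upper = upper),
    error = function(e) list(par = p0, value = fn(p0)))
  p <- sol$par
  structure(list(R0 = p[1], R_max = p[2], tau_align = p[3],
                 delta_R = p[2] - p[1], trend = trend,
                 p_trend = unname(ct$p.value), n_window = length(t)),
            class = "align_fit")
}

## ---- cohort summary -------------------------------------------------------

#' Cohort summary statistics and group comparisons
#'
#' Per-group medians and inter-quartile ranges of fit parameters,
#' two-sided Wilcoxon rank-sum tests between two groups, and bootstrap
#' confidence intervals of the medians.
#'
#' @param params data frame of per-cell fit parameters.
#' @param group factor/character column name identifying the groups
#'   (>= 2 groups, each with >= 2 members).
#' @param n_boot bootstrap iterations for the median CIs. Default 1000.
#' @param conf CI level. Default 0.95.
#' @param seed RNG seed for the bootstrap.
#' @return list with `summary` (group x parameter medians and IQR
#'   bounds, plus bootstrap CI of the median) and `tests` (parameter,
#'   Wilcoxon p-value) when exactly two groups are present.
#' @export
cohort_stats <- function(params, group = "group", n_boot = 1000,
                         conf = 0.95, seed = 1) {
  stopifnot(is.data.frame(params), group %in% names(params))
  if (!is.null(seed)) set.seed(seed)
  g <- as.factor(params[[group]])
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(table(g) < 2L)) stop("each group needs at least two members")
  num_cols <- setdiff(names(params)[vapply(params, is.numeric, logical(1))],
                      group)
  qa <- (1 - conf) / 2
  rows <- list()
  for (lev in levels(g)) for (p in num_cols) {
    v <- params[[p]][g == lev]
    v <- v[is.finite(v)]
    if (!length(v)) next
    boots <- vapply(seq_len(n_boot), function(i)
      stats::median(sample(v, replace = TRUE)), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      group = lev, parameter = p, n = length(v),
      median = stats::median(v),
      q25 = unname(stats::quantile(v, 0.25)),
      q75 = unname(stats::quantile(v, 0.75)),
      ci_lo = unname(stats::quantile(boots, qa)),
      ci_hi = unname(stats::quantile(boots, 1 - qa)))
  }
  summary <- do.call(rbind, rows)
  tests <- NULL
  if (nlevels(g) == 2L) {
    tests <- do.call(rbind, lapply(num_cols, function(p) {
      v1 <- params[[p]][g == levels(g)[1]]
      v2 <- params[[p]][g == levels(g)[2]]
      pv <- tryCatch(
        suppressWarnings(stats::wilcox.test(v1, v2)$p.value),
        error = function(e) NA_real_)
      data.frame(parameter = p, p_value = pv)
    }))
  }
  list(summary = summary, tests = tests)
}

## ---- linescan edge width --------------------------------------------------

# bilinear sampling of img at fractional (row, col) positions
interp_bilinear <- function(img, rr, cc) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- pmin(pmax(rr, 1), nr); cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(rr), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- rr - r0; fc <- cc - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Ridge width along a linescan (FWHM)
#'
#' Samples the image along a segment crossing a ridge, subtracts the
#' profile baseline, normalizes the peak to 1 and returns the full
#' width at half maximum in nanometres.
#'
#' @param img intensity matrix (e.g., Imax).
#' @param from,to (row, col) endpoints of the linescan.
#' @param pixel_size_nm pixel size.
#' @param n_samples samples along the segment.
#' @param min_contrast minimum (max - baseline) contrast; flatter
#'   profiles raise an error.
#' @return list: `width_nm`, `profile` data frame (pos_nm, value,
#'   normalized).
#' @export
measure_edge_width <- function(img, from, to, pixel_size_nm = 60,
                               n_samples = 201, min_contrast = 1e-6) {
  s <- seq(0, 1, length.out = n_samples)
  rr <- from[1] + s * (to[1] - from[1])
  cc <- from[2] + s * (to[2] - from[2])
  prof <- interp_bilinear(img, rr, cc)
  base <- min(prof)
  contrast <- max(prof) - base
  if (contrast <= min_contrast) stop("no ridge peak found along linescan")
  norm <- (prof - base) / contrast
  pk <- which.max(norm)
  if (pk == 1L || pk == n_samples) stop("ridge peak lies on the linescan boundary")
  cross <- function(idx_range, backward) {
    seqi <- if (backward) rev(idx_range) else idx_range
    for (j in seq_len(length(seqi) - 1L)) {
      a <- seqi[j]; b <- seqi[j + 1L]
      if (norm[a] >= 0.5 && norm[b] < 0.5) {
        frac <- (norm[a] - 0.5) / (norm[a] - norm[b])
        return(a + frac * (b - a))
      }
    }
    NA_real_
  }
  left <- cross(1:pk, backward = TRUE)
  right <- cross(pk:n_samples, backward = FALSE)
  if (is.na(left) || is.na(right))
    stop("half-maximum crossing not found on both sides of the peak")
  step_px <- sqrt(sum((c(to[1], to[2]) - c(from[1], from[2]))^2)) /
    (n_samples - 1)
  pos_nm <- (seq_len(n_samples) - 1) * step_px * pixel_size_nm
  list(width_nm = (right - left) * step_px * pixel_size_nm,
       profile = data.frame(pos_nm = pos_nm, value = prof,
                            normalized = norm))
}

## ---- track extraction -----------------------------------------------------

#' Measure a platelet track from per-timepoint orientation maps
#'
#' Computes T(t) (via [tension_area()]) and R(t) (via
#' [alignment_parameter()] over valid supra-threshold pixels) for every
#' frame.
#'
#' @param maps list of `orientation_map`s.
#' @param time_min frame times, minutes.
#' @param threshold,background_mask,k threshold rule for the tension
#'   area (see [tension_area()]).
#' @return a [platelet_track()].
#' @export
measure_track <- function(maps, time_min, threshold = NULL,
                          background_mask = NULL, k = 3) {
  stopifnot(length(maps) == length(time_min))
  Tv <- numeric(length(maps)); Rv <- rep(NA_real_, length(maps))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    thr <- threshold
    if (is.null(thr)) {
      if (is.null(background_mask))
        stop("need either an explicit threshold or a background_mask")
      bg <- m$i_max[background_mask]
      thr <- mean(bg) + k * stats::sd(bg)
    }
    Tv[i] <- tension_area(m, threshold = thr)
    sel <- m$valid & m$i_max > thr
    if (any(sel)) Rv[i] <- alignment_parameter(m$phi[sel])
  }
  platelet_track(time_min, Tv, Rv)
}
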