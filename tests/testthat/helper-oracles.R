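# Independent oracles and small fixture builders used across the suite.

# Dense least-squares fit of I = A sin^2(alpha - phi) + c, independent of
# the package's demodulation path: sample the curve densely, reparametrize
# as I = b0 + bc cos(2a) + bs sin(2a), solve by lm(), and read phi/A/c off
# the linear coefficients (bc = -(A/2) cos 2phi, bs = -(A/2) sin 2phi).
ls_fit_dense <- function(phi, A, c, n_alpha = 360) {
  a <- seq(0, 180, length.out = n_alpha + 1)[-(n_alpha + 1)]
  I <- A * sin((a - phi) * pi / 180)^2 + c
  X <- cbind(1, cos(2 * a * pi / 180), sin(2 * a * pi / 180))
  beta <- unname(stats::coef(stats::lm.fit(X, I)))
  A_ls <- 2 * sqrt(beta[2]^2 + beta[3]^2)
  phi_ls <- (atan2(-beta[3], -beta[2]) / 2) * 180 / pi
  list(phi = wrap_axial(phi_ls), A = A_ls, c = beta[1] - A_ls / 2)
}

# Noise-free polarization triplet for a given per-pixel truth
make_truth_triplet <- function(phi, theta, i_max, alphas = alpha_triplet(),
                               b = 0.069) {
  imgs <- lapply(as.numeric(alphas), function(a)
    forward_intensity(phi, theta, i_max, a, b))
  polarization_triplet(imgs, alphas)
}

# Flat (uniform-value) montage
flat_montage <- function(value, dim_px = 16, phases = 5, baseline = 200) {
  sim_montage(array(value, c(dim_px, dim_px, 3 * phases)),
              phases = phases, camera_baseline = baseline)
}

expect_axial_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(axial_dist(a, b)), tol)
}
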