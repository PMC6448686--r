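# shared fixtures and independent oracles, built in code at test time

# wet-softwood SANS-like truth (correlation peak prominent)
sans_truth <- function() reference_params("sans_wet_pine")
# wet-softwood SAXS-like truth (cylinder shoulder prominent, no Gaussian)
saxs_truth <- function() reference_params("saxs_wet_pine")

log_q_grid <- function(qmin, qmax, n = 120) {
  exp(seq(log(qmin), log(qmax), length.out = n))
}

# smallest angular distance on the 360-degree circle
.ang_diff_test <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# independent J1 evaluation by power series (for the form-factor oracle)
bessel_j1_series <- function(x, terms = 40) {
  k <- 0:(terms - 1)
  sum((-1)^k / (factorial(k) * factorial(k + 1)) * (x / 2)^(2 * k + 1))
}

# independent evaluation of a single 1D paracrystalline factor by summing
# its Fourier series  Z = 1 + 2 sum_n g^n cos(n t)
paracrystal_factor_series <- function(t, g, n_max = 4000) {
  n <- seq_len(n_max)
  1 + 2 * sum(g^n * cos(n * t))
}

# brute-force psi-averaged lattice factor in plain vectorized R
brute_psi_avg <- function(q, a, da, n_psi) {
  psi <- 2 * pi * (0:(n_psi - 1)) / n_psi
  g <- exp(-0.5 * q^2 * da^2)
  vapply(seq_along(q), function(i) {
    gi <- g[i]
    z1 <- (1 - gi^2) / (1 - 2 * gi * cos(q[i] * a * cos(psi)) + gi^2)
    z2 <- (1 - gi^2) / (1 - 2 * gi * cos(q[i] * a * cos(psi - pi / 3)) + gi^2)
    mean(z1 * z2)
  }, numeric(1))
}

# brute-force cylinder-lattice intensity with denser psi and radius grids,
# fully independent of the package's evaluation path
brute_i_cyl <- function(q, rbar, dr_sd, a, da, k = 3, n_r = 110, n_psi = 10010) {
  if (dr_sd > 0) {
    nodes <- seq(max(0, rbar - k * dr_sd), rbar + k * dr_sd,
                 length.out = n_r)
    w <- dnorm(nodes, rbar, dr_sd); w <- w / sum(w)
  } else {
    nodes <- rbar; w <- 1
  }
  fmat <- vapply(nodes, function(R) {
    x <- q * R
    ifelse(x > 0, pi * R^2 * 2 * besselJ(x, 1) / x, pi * R^2)
  }, numeric(length(q)))
  fmat <- matrix(fmat, nrow = length(q))
  m1 <- drop(fmat %*% w)
  m2 <- drop(fmat^2 %*% w)
  # turning point from a dense scan of the reduced-variable average
  x_scan <- seq(0.02, 12, by = 0.002)
  z_scan <- brute_psi_avg(x_scan / a, a, da, 2001)
  d <- diff(z_scan)
  i0 <- which(d[-1] > 0 & d[-length(d)] < 0)[1] + 1L
  q0 <- x_scan[i0] / a
  z <- brute_psi_avg(q, a, da, n_psi)
  z[q < q0] <- z_scan[i0]
  m2 - m1^2 + m1^2 * z
}

# small noise-free fibre-symmetric test pattern
tiny_pattern <- function(...) {
  simulate_pattern2d(geometry = list(beam_center_x = 48.5,
                                     beam_center_y = 48.5,
                                     pixel_size = 4, distance = 1200,
                                     wavelength = 6),
                     shape = c(96L, 96L), ...)
}

# synthetic equatorial WAXS curve from per-reflection (d, L) pairs in nm
waxs_curve_from_dL <- function(d_nm, L_nm, amps = c(0.6, 0.5, 1.0),
                               amorphous = c(center = 1.4, sd = 0.3,
                                             amplitude = 0.4),
                               background = c(intercept = 0.15,
                                              slope = -0.02),
                               q = seq(0.45, 2.3, length.out = 400)) {
  centres <- 2 * pi / (10 * d_nm)
  breadths <- 2 * pi / (10 * L_nm)
  sds <- breadths / sqrt(2 * pi)
  I <- background[["intercept"]] + background[["slope"]] * q +
    amorphous[["amplitude"]] *
      exp(-(q - amorphous[["center"]])^2 / (2 * amorphous[["sd"]]^2))
  for (j in seq_along(centres))
    I <- I + amps[j] * exp(-(q - centres[j])^2 / (2 * sds[j]^2))
  curve1d(q, I, metadata = list(truth_d = d_nm, truth_L = L_nm))
}

# reference (d, L) rows in nm for the birch-like synthetic WAXS fixture
birch_waxs_truth <- function() {
  list(d = c(0.5780, 0.5211, 0.3891), L = c(2.95, 4.73, 3.09))
}
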