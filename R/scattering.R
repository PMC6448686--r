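#' Cross-section scattering amplitude of an infinitely long cylinder
#'
#' Amplitude of the circular cross section, `f(q, R) = pi R^2 * 2 J1(qR)/(qR)`,
#' with the q = 0 limit `pi R^2` (the cross-sectional area). Contrast and
#' number-density prefactors are absorbed into the model scale `A`.
#'
#' @param q Scattering vector magnitude(s), 1/angstrom, >= 0.
#' @param R Cylinder radius (angstrom), > 0.
#' @return Numeric vector of amplitudes, same length as `q`.
#' @export
cylinder_amplitude <- function(q, R) {
  if (length(R) != 1L || R <= 0) stop("R must be a single positive value")
  if (any(q < 0)) stop("q must be >= 0")
  x <- q * R
  out <- rep(pi * R^2, length(q))
  nz <- x > 0
  out[nz] <- pi * R^2 * 2 * besselJ(x[nz], 1) / x[nz]
  out
}

#' Quadrature nodes and weights for the radius distribution
#'
#' Discretises the Gaussian radius distribution on `n_points` equally spaced
#' nodes covering `[max(0, R - k*dR), R + k*dR]` (the lower end is clipped at
#' zero). Weights are proportional to the Gaussian density at the nodes and
#' renormalised to sum to one. A zero-width distribution collapses to a
#' single unit-weight node at the mean.
#'
#' @param dist A [radius_distribution()].
#' @return A data frame with columns `node` (radius, angstrom) and `weight`.
#' @export
radius_quadrature <- function(dist) {
  stopifnot(inherits(dist, "radius_distribution"))
  if (dist$sd == 0)
    return(data.frame(node = dist$mean_radius, weight = 1))
  lo <- max(0, dist$mean_radius - dist$truncation_k * dist$sd)
  hi <- dist$mean_radius + dist$truncation_k * dist$sd
  nodes <- seq(lo, hi, length.out = dist$n_points)
  w <- dnorm(nodes, dist$mean_radius, dist$sd)
  data.frame(node = nodes, weight = w / sum(w))
}

#' Paracrystalline hexagonal lattice factor at fixed orientation
#'
#' Interference factor `Z1 * Z2` of a 2D hexagonal paracrystal with lattice
#' distortion of the second kind, for a crystal rotated by `psi`. The two
#' basis vectors lie at 0 and 60 degrees, each contributing
#' `Z_k = (1 - g^2) / (1 - 2 g cos(q a cos(psi - psi_k)) + g^2)` with
#' `g = exp(-q^2 da^2 / 2)`.
#'
#' @param q Scattering vector magnitude(s), 1/angstrom, > 0.
#' @param psi Crystal rotation angle (radians); scalar or same length as `q`.
#' @param lattice A [lattice_config()].
#' @return Numeric vector `Z1 * Z2 >= 0`.
#' @export
lattice_factor <- function(q, psi, lattice) {
  stopifnot(inherits(lattice, "lattice_config"))
  if (any(q <= 0)) stop("q must be > 0")
  a <- lattice$spacing
  g <- exp(-0.5 * q^2 * lattice$distortion^2)
  g2 <- g * g
  zk <- function(psik) {
    (1 - g2) / (1 - 2 * g * cos(q * a * cos(psi - psik)) + g2)
  }
  zk(0) * zk(pi / 3)
}

#' Orientation-averaged lattice factor
#'
#' Arithmetic mean of [lattice_factor()] over a uniform grid of the crystal
#' rotation angle psi on `[0, 2*pi)` (the rotation of the crystals about the
#' cylinder axis is assumed uniform). Depends on the parameters only through
#' the reduced variables `q*a` and `da/a`.
#'
#' @inheritParams lattice_factor
#' @param n_psi Number of psi grid points; defaults to `lattice$psi_points`.
#' @return Numeric vector of averaged lattice-factor values.
#' @export
psi_averaged_Z <- function(q, lattice, n_psi = lattice$psi_points) {
  stopifnot(inherits(lattice, "lattice_config"))
  if (any(q <= 0)) stop("q must be > 0")
  psi_avg_lattice_cpp(q * lattice$spacing,
                      lattice$distortion / lattice$spacing,
                      as.integer(n_psi))
}

#' Turning point of the averaged lattice factor
#'
#' Locates the first local minimum q0 of the orientation-averaged lattice
#' factor, scanning upward from low q, and the plateau value Z(q0) used to
#' continue the lattice factor as a constant below q0 (suppressing the
#' unphysical paracrystalline upturn at low q). The search runs in the
#' reduced variable `x = q*a`, so `q0*a` depends on `da/a` only.
#'
#' @param lattice A [lattice_config()] with `distortion > 0`.
#' @param x_max Upper end of the reduced-variable scan window (default 12).
#' @param n_scan Number of scan points (default 600).
#' @return An object of class `"modified_lattice"`: list with `q0`
#'   (1/angstrom), `plateau` (= Z(q0)), and the reduced location `x0 = q0*a`.
#' @export
turning_point <- function(lattice, x_max = 12, n_scan = 600L) {
  stopifnot(inherits(lattice, "lattice_config"))
  if (lattice$distortion <= 0)
    stop("turning point undefined for an undistorted lattice (da = 0)")
  dr <- lattice$distortion / lattice$spacing
  x <- seq(x_max / n_scan, x_max, length.out = n_scan)
  z <- psi_avg_lattice_cpp(x, dr, as.integer(lattice$psi_points))
  d <- diff(z)
  imin <- which(d[-1] > 0 & d[-length(d)] < 0)
  if (!length(imin))
    stop("no local minimum of the averaged lattice factor found; ",
         "degenerate lattice parameters (da/a = ", signif(dr, 3), ")")
  i <- imin[1] + 1L                       # first interior local minimum
  opt <- optimize(function(xx)
    psi_avg_lattice_cpp(xx, dr, as.integer(lattice$psi_points)),
    interval = c(x[i - 1L], x[i + 1L]), tol = 1e-9)
  structure(list(q0 = opt$minimum / lattice$spacing,
                 plateau = opt$objective,
                 x0 = opt$minimum),
            class = "modified_lattice")
}

#' @export
print.modified_lattice <- function(x, ...) {
  cat(sprintf("Lattice-factor turning point: q0 = %.4g 1/A (q0*a = %.4g), Z(q0) = %.4g\n",
              x$q0, x$x0, x$plateau))
  invisible(x)
}

#' Intensity of polydisperse cylinders on a distorted hexagonal lattice
#'
#' Decoupling-approximation intensity
#' \deqn{I_{cyl}(q) = \langle f^2\rangle_R - \langle f\rangle_R^2 +
#'   \langle f\rangle_R^2 \tilde Z(q),}
#' where the radius averages use [radius_quadrature()] and `Z-tilde` is the
#' orientation-averaged lattice factor, continued as the constant `Z(q0)`
#' below the turning point q0 (see [turning_point()]) to suppress the
#' unphysical low-q upturn of the paracrystalline interference function.
#'
#' @param q Scattering vector magnitude(s), 1/angstrom, > 0.
#' @param radius A [radius_distribution()].
#' @param lattice A [lattice_config()].
#' @param tp Optional precomputed [turning_point()] result (performance).
#' @return Numeric intensity vector, `>= 0`, continuous at q0.
#' @export
i_cyl <- function(q, radius, lattice, tp = NULL) {
  stopifnot(inherits(radius, "radius_distribution"))
  if (any(q <= 0)) stop("q must be > 0")
  quad <- radius_quadrature(radius)
  m1 <- numeric(length(q))
  m2 <- numeric(length(q))
  for (i in seq_len(nrow(quad))) {
    f <- cylinder_amplitude(q, quad$node[i])
    m1 <- m1 + quad$weight[i] * f
    m2 <- m2 + quad$weight[i] * f^2
  }
  if (lattice$distortion > 0) {
    if (is.null(tp)) tp <- turning_point(lattice)
    z <- psi_averaged_Z(q, lattice)
    z[q < tp$q0] <- tp$plateau
  } else {
    stop("i_cyl requires a distorted lattice (da > 0)")
  }
  m2 - m1^2 + m1^2 * z
}

#' Total equatorial model intensity
#'
#' Evaluates the composite equatorial model
#' `I(q) = A * I_cyl(q) + B * exp(-q^2/(2 sigma^2)) + C * q^(-alpha)`;
#' the Gaussian term is omitted when `p$gaussian_enabled` is `FALSE`.
#'
#' @param q Scattering vector magnitude(s), 1/angstrom, strictly > 0 (the
#'   power law diverges at q = 0).
#' @param p A [model_params()] object.
#' @return Numeric intensity vector.
#' @export
total_intensity <- function(q, p) {
  stopifnot(inherits(p, "model_params"))
  if (any(q <= 0)) stop("q must be > 0 (power-law term diverges at q = 0)")
  out <- p$A * i_cyl(q, p$radius, p$lattice)
  if (p$gaussian_enabled)
    out <- out + p$B * exp(-q^2 / (2 * p$sigma^2))
  out + p$C * q^(-p$alpha)
}

#' Plugin-style model function over a flat parameter vector
#'
#' Single-entry evaluation of the equatorial model from the flat parameter
#' representation of [params_to_config()] (lengths in nm, `sigma` in
#' 1/angstrom), suitable for registration in generic SAS fitting frameworks.
#'
#' @param q Scattering vector magnitude(s), 1/angstrom, > 0.
#' @param config Named numeric vector or list; see [params_from_config()].
#' @param ... Passed to [params_from_config()] (e.g. `gaussian_enabled`,
#'   `psi_points`).
#' @return Numeric intensity vector.
#' @export
sas_model <- function(q, config, ...) {
  total_intensity(q, params_from_config(config, ...))
}
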