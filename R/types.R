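#' Gaussian distribution of the microfibril radius
#'
#' Describes the polydispersity of the cylinder (microfibril) cross-section
#' radius as a Gaussian with mean `mean_radius` and standard deviation `sd`,
#' discretised for numerical averaging by [radius_quadrature()]. All lengths
#' are in angstrom.
#'
#' @param mean_radius Mean radius R-bar (angstrom), > 0.
#' @param sd Standard deviation Delta-R of the radius (angstrom), >= 0.
#'   `sd = 0` collapses the distribution to a single point.
#' @param n_points Number of quadrature nodes (odd, >= 1; default 11).
#' @param truncation_k Half-width of the quadrature interval in units of
#'   `sd` (default 3); the interval is clipped at zero from below.
#' @return An object of class `"radius_distribution"`.
#' @seealso [radius_quadrature()], [lattice_config()], [model_params()]
#' @export
radius_distribution <- function(mean_radius, sd, n_points = 11L,
                                truncation_k = 3) {
  stopifnot(is.numeric(mean_radius), length(mean_radius) == 1L,
            is.numeric(sd), length(sd) == 1L)
  if (mean_radius <= 0) stop("mean_radius must be > 0")
  if (sd < 0) stop("radius sd must be >= 0")
  n_points <- as.integer(n_points)
  if (n_points < 1L || n_points %% 2L == 0L)
    stop("n_points must be an odd integer >= 1")
  if (truncation_k <= 0) stop("truncation_k must be > 0")
  structure(list(mean_radius = mean_radius, sd = sd, n_points = n_points,
                 truncation_k = truncation_k),
            class = "radius_distribution")
}

#' Paracrystalline hexagonal lattice configuration
#'
#' Lattice of microfibril centre points: hexagonal with centre-to-centre
#' distance `spacing` and paracrystalline distortion of the second kind with
#' standard deviation `distortion` per lattice direction. Lengths in
#' angstrom.
#'
#' @param spacing Centre-to-centre distance a (angstrom), > 0.
#' @param distortion Standard deviation Delta-a of the lattice-vector length
#'   (angstrom), >= 0.
#' @param psi_points Number of grid points for the orientational average over
#'   the crystal rotation angle psi, uniform on `[0, 2*pi)` (default 1001).
#' @return An object of class `"lattice_config"`.
#' @export
lattice_config <- function(spacing, distortion, psi_points = 1001L) {
  stopifnot(is.numeric(spacing), length(spacing) == 1L,
            is.numeric(distortion), length(distortion) == 1L)
  if (spacing <= 0) stop("lattice spacing must be > 0")
  if (distortion < 0) stop("lattice distortion must be >= 0")
  psi_points <- as.integer(psi_points)
  if (psi_points < 1L) stop("psi_points must be >= 1")
  structure(list(spacing = spacing, distortion = distortion,
                 psi_points = psi_points),
            class = "lattice_config")
}

#' Full parameter set of the equatorial intensity model
#'
#' Container for the parameters of the composite equatorial model
#' \deqn{I(q) = A I_{cyl}(q) + B \exp(-q^2 / 2\sigma^2) + C q^{-\alpha},}
#' where `I_cyl` is the intensity of polydisperse infinitely long cylinders
#' on a distorted hexagonal lattice (see [i_cyl()]). The Gaussian term
#' (scale `B`) approximates scattering from larger pores and can be disabled;
#' the power law (scale `C`) models surface scattering from pores and lumina.
#'
#' @param A Scale of the cylinder term, >= 0.
#' @param B Scale of the Gaussian term centred at q = 0, >= 0.
#' @param sigma Standard deviation of the Gaussian term in q (1/angstrom);
#'   must be positive when the Gaussian term is enabled.
#' @param C Scale of the power-law term, >= 0.
#' @param alpha Power-law exponent, > 0 (close to 4 for surface scattering).
#' @param radius A [radius_distribution()].
#' @param lattice A [lattice_config()].
#' @param gaussian_enabled Logical; include the B-term? Default `TRUE`.
#' @return An object of class `"model_params"`.
#' @export
model_params <- function(A, B = 0, sigma = 0.02, C = 0, alpha = 4,
                         radius, lattice, gaussian_enabled = TRUE) {
  stopifnot(inherits(radius, "radius_distribution"),
            inherits(lattice, "lattice_config"))
  if (A < 0 || B < 0 || C < 0) stop("scale factors A, B, C must be >= 0")
  if (alpha <= 0) stop("alpha must be > 0")
  if (gaussian_enabled && sigma <= 0)
    stop("sigma must be > 0 when the Gaussian term is enabled")
  structure(list(A = A, B = B, sigma = sigma, C = C, alpha = alpha,
                 radius = radius, lattice = lattice,
                 gaussian_enabled = isTRUE(gaussian_enabled)),
            class = "model_params")
}

#' @export
print.radius_distribution <- function(x, ...) {
  cat(sprintf(
    "Radius distribution: R = %.3g A, dR = %.3g A (%d nodes, +-%g sd)\n",
    x$mean_radius, x$sd, x$n_points, x$truncation_k))
  invisible(x)
}

#' @export
print.lattice_config <- function(x, ...) {
  cat(sprintf(
    "Hexagonal paracrystal: a = %.3g A, da = %.3g A (da/a = %.3g), %d psi points\n",
    x$spacing, x$distortion, x$distortion / x$spacing, x$psi_points))
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Equatorial intensity model parameters\n")
  cat(sprintf("  cylinder term : A = %.4g\n", x$A))
  if (x$gaussian_enabled)
    cat(sprintf("  Gaussian term : B = %.4g, sigma = %.4g 1/A\n", x$B, x$sigma))
  else
    cat("  Gaussian term : disabled\n")
  cat(sprintf("  power law     : C = %.4g, alpha = %.4g\n", x$C, x$alpha))
  print(x$radius)
  print(x$lattice)
  invisible(x)
}

# canonical order of the flat user-facing parameter vector (lengths in nm)
.flat_param_names <- c("scale_A", "d_mean", "dR_rel", "a", "da_rel",
                       "scale_B", "sigma", "scale_C", "alpha")

#' Convert model parameters to/from a flat named vector
#'
#' The flat representation uses the field's reporting conventions: lengths in
#' nanometres (`d_mean` is the mean cylinder *diameter*, `a` the lattice
#' spacing), relative polydispersities `dR_rel = dR/R` and `da_rel = da/a`,
#' and `sigma` in 1/angstrom (a width in q). This is the parameter vector
#' used by the fitting engine and by configuration files.
#'
#' @param p A [model_params()] object.
#' @return `params_to_config()`: a named numeric vector with elements
#'   `scale_A, d_mean, dR_rel, a, da_rel, scale_B, sigma, scale_C, alpha`
#'   plus attribute `gaussian_enabled`.
#' @export
params_to_config <- function(p) {
  stopifnot(inherits(p, "model_params"))
  out <- c(scale_A = p$A,
           d_mean = 2 * p$radius$mean_radius / 10,
           dR_rel = if (p$radius$mean_radius > 0)
             p$radius$sd / p$radius$mean_radius else 0,
           a = p$lattice$spacing / 10,
           da_rel = p$lattice$distortion / p$lattice$spacing,
           scale_B = p$B, sigma = p$sigma, scale_C = p$C, alpha = p$alpha)
  attr(out, "gaussian_enabled") <- p$gaussian_enabled
  out
}

#' @rdname params_to_config
#' @param config Named numeric vector (or list coercible to one) with the
#'   elements listed above; missing `scale_B`/`sigma` disable the Gaussian
#'   term.
#' @param gaussian_enabled Logical override; default taken from the config
#'   attribute, else `TRUE` when `scale_B` is present.
#' @param n_points,psi_points,truncation_k Discretisation settings passed to
#'   [radius_distribution()] and [lattice_config()].
#' @export
params_from_config <- function(config, gaussian_enabled = NULL,
                               n_points = 11L, psi_points = 1001L,
                               truncation_k = 3) {
  cfg <- unlist(config)
  need <- c("scale_A", "d_mean", "dR_rel", "a", "da_rel", "scale_C", "alpha")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("missing model parameter(s): ", paste(miss, collapse = ", "))
  if (is.null(gaussian_enabled)) {
    gaussian_enabled <- attr(config, "gaussian_enabled")
    if (is.null(gaussian_enabled))
      gaussian_enabled <- "scale_B" %in% names(cfg) && !is.na(cfg[["scale_B"]])
  }
  rbar <- cfg[["d_mean"]] * 10 / 2           # nm diameter -> A radius
  model_params(
    A = cfg[["scale_A"]],
    B = if ("scale_B" %in% names(cfg)) cfg[["scale_B"]] else 0,
    sigma = if ("sigma" %in% names(cfg)) cfg[["sigma"]] else 0.02,
    C = cfg[["scale_C"]], alpha = cfg[["alpha"]],
    radius = radius_distribution(rbar, cfg[["dR_rel"]] * rbar,
                                 n_points = n_points,
                                 truncation_k = truncation_k),
    lattice = lattice_config(cfg[["a"]] * 10, cfg[["da_rel"]] * cfg[["a"]] * 10,
                             psi_points = psi_points),
    gaussian_enabled = gaussian_enabled)
}

#' Reference model parameter sets
#'
#' Bundled parameter sets characteristic of equatorial small-angle scattering
#' from wet softwood, as reported in the literature for Scots pine: one for
#' SANS-like data (correlation peak near q = 0.15 1/angstrom prominent,
#' Gaussian term present) and one for SAXS-like data (cylinder shoulder
#' prominent, no Gaussian term). Useful as simulation truths and as fit
#' starting points.
#'
#' @param which One of `"sans_wet_pine"`, `"saxs_wet_pine"`.
#' @return A [model_params()] object.
#' @export
reference_params <- function(which = c("sans_wet_pine", "saxs_wet_pine")) {
  which <- match.arg(which)
  cfg <- switch(which,
    sans_wet_pine = c(scale_A = 1.7, d_mean = 2.04, dR_rel = 0.2,
                      a = 4.21, da_rel = 0.271, scale_B = 2.4,
                      sigma = 1.48e-2, scale_C = 0.31e-7, alpha = 4.34),
    saxs_wet_pine = c(scale_A = 1.5e3, d_mean = 2.51, dR_rel = 0.207,
                      a = 3.75, da_rel = 0.41, scale_C = 0.04e-3,
                      alpha = 4.2))
  params_from_config(cfg,
                     gaussian_enabled = which == "sans_wet_pine")
}
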