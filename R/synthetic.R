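#' Simulate a 1D equatorial curve from the model
#'
#' Evaluates the equatorial model on a q grid and applies multiplicative
#' Gaussian noise, `I_obs = I_model * (1 + eps)` with
#' `eps ~ Normal(0, rel_noise)`; the reported uncertainty is
#' `rel_noise * I_model`. The seed fully determines the output.
#'
#' @param params A [model_params()] truth.
#' @param q Strictly increasing q grid (1/angstrom), > 0.
#' @param rel_noise Relative noise level (default 0.02; 0 gives the exact
#'   model curve).
#' @param seed Integer random seed.
#' @return A [curve1d()]; the truth parameters and seed are recorded in the
#'   metadata.
#' @export
simulate_curve <- function(params, q, rel_noise = 0.02, seed = 1L) {
  stopifnot(inherits(params, "model_params"), rel_noise >= 0)
  I_model <- total_intensity(q, params)
  set.seed(seed)
  I_obs <- I_model * (1 + rnorm(length(q), 0, rel_noise))
  sigma <- if (rel_noise > 0) rel_noise * I_model else NULL
  curve1d(q, I_obs, sigma,
          metadata = list(truth = params_to_config(params),
                          rel_noise = rel_noise, seed = seed,
                          simulated = TRUE))
}

#' Simulate a fibre-symmetric 2D detector pattern
#'
#' Builds the expected pixel intensity as
#' `iso_profile(q) + eq_profile(q) * [G(phi; phi0, sd) + G(phi; phi0+180, sd)]`
#' and draws Poisson counts at the given exposure scale. Emulates the
#' anisotropic scattering of wood with its vertical fibre axis: an isotropic
#' background plus equatorial arcs.
#'
#' @param geometry Geometry list as in [pattern2d()].
#' @param shape Detector shape `c(rows, cols)` (default `c(128, 128)`).
#' @param iso_profile Function of q giving the isotropic radial profile.
#' @param eq_profile Function of q giving the equatorial radial profile.
#' @param phi0 Arc centre (degrees; default 0, the equator for a vertical
#'   fibre axis).
#' @param phi_sd Azimuthal Gaussian width of the arcs (degrees, default 15).
#' @param counts Exposure scale: expected counts = `counts *` model pixel
#'   intensity (default 1000). `counts = 0` returns the noise-free pattern.
#' @param mask Optional logical mask (`TRUE` = excluded).
#' @param seed Integer random seed.
#' @return A [pattern2d()]; in counts units when `counts > 0`.
#' @export
simulate_pattern2d <- function(geometry = list(beam_center_x = 64.5,
                                               beam_center_y = 64.5,
                                               pixel_size = 4,
                                               distance = 1200,
                                               wavelength = 6),
                               shape = c(128L, 128L),
                               iso_profile = function(q) 1 / (1 + (q / 0.05)^2),
                               eq_profile = function(q)
                                 2 * exp(-(q - 0.15)^2 / (2 * 0.03^2)),
                               phi0 = 0, phi_sd = 15, counts = 1000,
                               mask = NULL, seed = 1L) {
  blank <- pattern2d(matrix(0, shape[1], shape[2]), geometry, mask)
  maps <- pixel_qphi(blank)
  d1 <- .ang_diff(maps$phi, phi0)
  d2 <- .ang_diff(maps$phi, phi0 + 180)
  arcs <- exp(-d1^2 / (2 * phi_sd^2)) + exp(-d2^2 / (2 * phi_sd^2))
  expected <- iso_profile(maps$q) + eq_profile(maps$q) * arcs
  expected[expected < 0] <- 0
  if (counts > 0) {
    set.seed(seed)
    obs <- matrix(rpois(length(expected), counts * expected),
                  nrow(expected), ncol(expected))
  } else {
    obs <- expected
  }
  pattern2d(obs, geometry, mask)
}

#' Simulate a drying series of equatorial curves
#'
#' Generates an ordered sequence of noisy curves whose truth parameters ramp
#' linearly (in the flat parameter space) from `params_start` to
#' `params_end`, emulating in situ measurements during drying: the
#' interfibrillar distance contracts by roughly 20 percent, the microfibril
#' diameter shrinks, and the low-q power-law scale grows.
#'
#' @param params_start,params_end [model_params()] at the first and last
#'   time point. Defaults emulate a wet-to-dry softwood drying run.
#' @param n_steps Number of time points (default 12).
#' @param q Common q grid (default 80 points on `[0.03, 0.5]` 1/angstrom,
#'   the short-detector-distance window).
#' @param rel_noise Relative noise per curve (default 0.02).
#' @param seed Integer base seed; curve i uses `seed + i - 1`.
#' @return List of [curve1d()] objects; each carries its truth in metadata.
#' @export
simulate_drying_series <- function(params_start = NULL, params_end = NULL,
                                   n_steps = 12L,
                                   q = seq(0.03, 0.5, length.out = 80),
                                   rel_noise = 0.02, seed = 1L) {
  if (is.null(params_start))
    params_start <- params_from_config(
      c(scale_A = 1.5e3, d_mean = 2.5, dR_rel = 0.2, a = 4.2, da_rel = 0.3,
        scale_C = 4e-5, alpha = 4), gaussian_enabled = FALSE)
  if (is.null(params_end))
    params_end <- params_from_config(
      c(scale_A = 0.3e3, d_mean = 2.2, dR_rel = 0.24, a = 3.3, da_rel = 0.3,
        scale_C = 4e-3, alpha = 4), gaussian_enabled = FALSE)
  cfg0 <- params_to_config(params_start)
  cfg1 <- params_to_config(params_end)
  ge <- params_start$gaussian_enabled
  lapply(seq_len(n_steps), function(i) {
    t <- if (n_steps == 1L) 0 else (i - 1) / (n_steps - 1)
    cfg <- (1 - t) * cfg0 + t * cfg1
    simulate_curve(params_from_config(cfg, gaussian_enabled = ge), q,
                   rel_noise = rel_noise, seed = seed + i - 1L)
  })
}

#' Parameter-recovery study on simulated curves
#'
#' Repeatedly simulates noisy curves from a truth parameter set and refits
#' them with randomly perturbed starting values, the standard protocol for
#' validating the fitting engine. Each replicate i uses seed
#' `seed_base + i` for both the noise and the start perturbation; starting
#' values of free parameters are multiplied by independent
#' `Uniform(1 - perturb, 1 + perturb)` factors (clipped to the recipe
#' bounds).
#'
#' @param truth A [model_params()] used to generate the data.
#' @param q q grid for the simulated curves.
#' @param n_rep Number of replicates (default 20).
#' @param rel_noise Relative noise (default 0.02).
#' @param perturb Relative start perturbation (default 0.2).
#' @param fixed Parameters held fixed at truth during the fits.
#' @param seed_base Integer base seed (replicate i uses `seed_base + i`).
#' @return A data frame with one row per replicate: the fitted flat
#'   parameters, `redchi2` and `converged`.
#' @export
recovery_study <- function(truth, q, n_rep = 20L, rel_noise = 0.02,
                           perturb = 0.2, fixed = character(),
                           seed_base = 0L) {
  stopifnot(inherits(truth, "model_params"))
  truth_cfg <- params_to_config(truth)
  rows <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    curve <- simulate_curve(truth, q, rel_noise = rel_noise,
                            seed = seed_base + i)
    set.seed(seed_base + i)
    start <- truth_cfg
    free <- setdiff(names(start), fixed)
    start[free] <- start[free] *
      runif(length(free), 1 - perturb, 1 + perturb)
    start <- pmin(pmax(start, .default_lower[names(start)]),
                  .default_upper[names(start)])
    rec <- fit_recipe(structure(start,
                                gaussian_enabled = truth$gaussian_enabled),
                      fixed = fixed, rel_error = rel_noise)
    fit <- fit_curve(curve, rec)
    rows[[i]] <- data.frame(replicate = i, t(fit$par),
                            redchi2 = fit$redchi2,
                            converged = fit$converged,
                            check.names = FALSE)
  }
  do.call(rbind, rows)
}
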