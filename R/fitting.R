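.default_lower <- c(scale_A = 0, d_mean = 0.5, dR_rel = 0, a = 1.5,
                    da_rel = 0.03, scale_B = 0, sigma = 1e-3,
                    scale_C = 0, alpha = 2)
.default_upper <- c(scale_A = Inf, d_mean = 6, dR_rel = 0.6, a = 10,
                    da_rel = 0.9, scale_B = Inf, sigma = 0.2,
                    scale_C = Inf, alpha = 7)

#' Fit recipe: initial values, fixes, bounds, weighting, q range
#'
#' Declarative description of how a curve is to be fitted: initial model
#' parameters, which parameters are held fixed, per-parameter bounds, the
#' relative-error weighting (2 percent by default, i.e. residuals are
#' `(I_data - I_model) / (0.02 I_data)`), and the q fit range. Parameters are
#' named as in [params_to_config()] (lengths in nm). When the initial
#' parameter set has the Gaussian term disabled, `scale_B` and `sigma` are
#' dropped from the fit entirely.
#'
#' @param init A [model_params()] object or flat named config vector.
#' @param fixed Character vector of parameter names held fixed at their
#'   initial values.
#' @param lower,upper Named numeric vectors overriding the default bounds
#'   for some or all parameters (e.g. `upper = c(sigma = 0.08)`).
#' @param rel_error Relative intensity error used to weight the residuals
#'   (default 0.02).
#' @param q_range Length-2 numeric, q fit window (1/angstrom); `NULL` fits
#'   the full measured range.
#' @return An object of class `"fit_recipe"`.
#' @export
fit_recipe <- function(init, fixed = character(), lower = NULL, upper = NULL,
                       rel_error = 0.02, q_range = NULL) {
  if (inherits(init, "model_params")) init <- params_to_config(init)
  gaussian_enabled <- isTRUE(attr(init, "gaussian_enabled")) ||
    is.null(attr(init, "gaussian_enabled"))
  cfg <- unlist(init)
  names_all <- .flat_param_names
  if (!gaussian_enabled) names_all <- setdiff(names_all, c("scale_B", "sigma"))
  miss <- setdiff(setdiff(names_all, c("scale_B", "sigma")), names(cfg))
  if (length(miss))
    stop("initial values missing for: ", paste(miss, collapse = ", "))
  cfg <- cfg[intersect(.flat_param_names, names(cfg))]
  lo <- .default_lower[names_all]
  up <- .default_upper[names_all]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper
  # user bounds for parameters not in play (e.g. sigma with the Gaussian
  # term disabled) are ignored
  lo <- lo[names_all]; up <- up[names_all]
  init_v <- pmin(pmax(cfg[names_all], lo), up)
  bad <- which(cfg[names_all] < lo | cfg[names_all] > up)
  if (length(bad))
    stop("initial value(s) outside bounds: ",
         paste(names_all[bad], collapse = ", "))
  fixed <- intersect(fixed, names_all)
  if (rel_error <= 0) stop("rel_error must be > 0")
  structure(list(init = init_v, fixed = fixed, lower = lo, upper = up,
                 rel_error = rel_error, q_range = q_range,
                 gaussian_enabled = gaussian_enabled),
            class = "fit_recipe")
}

#' @export
print.fit_recipe <- function(x, ...) {
  cat("Fit recipe (", if (x$gaussian_enabled) "with" else "without",
      " Gaussian term)\n", sep = "")
  flag <- ifelse(names(x$init) %in% x$fixed, "*", " ")
  for (i in seq_along(x$init))
    cat(sprintf("  %-8s%s init %.4g  bounds [%.3g, %.3g]\n",
                names(x$init)[i], flag[i], x$init[i], x$lower[i], x$upper[i]))
  if (length(x$fixed)) cat("  (* = fixed)\n")
  cat(sprintf("  relative error %.3g", x$rel_error))
  if (!is.null(x$q_range))
    cat(sprintf(", q range [%.4g, %.4g] 1/A", x$q_range[1], x$q_range[2]))
  cat("\n")
  invisible(x)
}

# model intensity from the recipe's parameterisation
.recipe_model <- function(q, par_all, gaussian_enabled) {
  total_intensity(q, params_from_config(par_all,
                                        gaussian_enabled = gaussian_enabled))
}

#' Weighted bounded least-squares fit of the equatorial model
#'
#' Fits the composite equatorial model to a 1D curve by
#' Levenberg-Marquardt minimisation of
#' `sum(((I_data - I_model) / (rel_error * I_data))^2)` with box bounds and
#' fixed parameters as declared in the recipe. Uncertainties for free
#' parameters come from the Jacobian covariance at the optimum.
#'
#' @param curve A [curve1d()].
#' @param recipe A [fit_recipe()].
#' @param maxiter Maximum optimizer iterations (default 200).
#' @return An object of class `"sas_fit"`: list with `par` (full flat
#'   parameter vector at the optimum), `stderr` (`NA` for fixed parameters),
#'   `redchi2`, `converged`, `fixed`, `params` (a [model_params()]), and
#'   optimizer diagnostics.
#' @export
fit_curve <- function(curve, recipe, maxiter = 200L) {
  stopifnot(inherits(curve, "sas_curve"), inherits(recipe, "fit_recipe"))
  dat <- as.data.frame(curve)
  if (!is.null(recipe$q_range))
    dat <- dat[dat$q >= recipe$q_range[1] & dat$q <= recipe$q_range[2], ]
  free <- setdiff(names(recipe$init), recipe$fixed)
  if (nrow(dat) < 3 * length(free))
    stop("need at least 3x more data points (", nrow(dat),
         ") than free parameters (", length(free), ")")
  w <- recipe$rel_error * abs(dat$I)
  if (any(w == 0)) stop("zero intensities are incompatible with relative-error weighting")
  par_all <- recipe$init
  resid_fn <- function(p_free) {
    par_all[free] <- p_free
    m <- tryCatch(.recipe_model(dat$q, par_all, recipe$gaussian_enabled),
                  error = function(e) rep(NA_real_, nrow(dat)))
    r <- (dat$I - m) / w
    r[!is.finite(r)] <- 1e6
    r
  }
  fit <- minpack.lm::nls.lm(
    par = recipe$init[free], lower = recipe$lower[free],
    upper = recipe$upper[free], fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter))
  # info 5 = iteration cap: typically the optimizer polishing directions the
  # data barely constrain; a warm restart settles the convergence test
  restarts <- 0L
  while (fit$info == 5 && restarts < 2L) {
    fit <- minpack.lm::nls.lm(
      par = fit$par, lower = recipe$lower[free],
      upper = recipe$upper[free], fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter))
    restarts <- restarts + 1L
  }
  par_all[free] <- fit$par
  converged <- fit$info %in% c(1, 2, 3, 4)
  dof <- nrow(dat) - length(free)
  redchi2 <- fit$deviance / max(dof, 1)
  stderr <- setNames(rep(NA_real_, length(par_all)), names(par_all))
  # covariance restricted to parameters the data actually determine; a
  # parameter whose Jacobian column is negligible (e.g. a term buried under
  # the dominant one) keeps stderr = NA rather than a meaningless number
  se <- rep(NA_real_, length(free))
  h <- fit$hessian
  dh <- sqrt(abs(diag(h)))
  det_ok <- dh > max(dh) * 1e-8
  covm <- tryCatch(solve(h[det_ok, det_ok, drop = FALSE]) * redchi2,
                   error = function(e) NULL)
  if (!is.null(covm)) se[det_ok] <- sqrt(pmax(diag(covm), 0))
  stderr[free] <- se
  structure(list(par = par_all, stderr = stderr, redchi2 = redchi2,
                 converged = converged, fixed = recipe$fixed,
                 gaussian_enabled = recipe$gaussian_enabled,
                 n_points = nrow(dat), info = fit$info,
                 message = fit$message,
                 params = params_from_config(
                   par_all, gaussian_enabled = recipe$gaussian_enabled)),
            class = "sas_fit")
}

#' @export
print.sas_fit <- function(x, ...) {
  cat("Equatorial model fit:",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(reduced chi2 = %.4g, %d points)\n", x$redchi2, x$n_points))
  flag <- ifelse(names(x$par) %in% x$fixed, "*", " ")
  for (i in seq_along(x$par)) {
    se <- if (is.na(x$stderr[i])) "" else sprintf(" +- %.3g", x$stderr[i])
    cat(sprintf("  %-8s%s %.4g%s\n", names(x$par)[i], flag[i], x$par[i], se))
  }
  if (length(x$fixed)) cat("  (* = fixed)\n")
  invisible(x)
}

#' Sequential fitting of an ordered curve series
#'
#' Fits each curve of an ordered series (e.g. measurements during drying),
#' warm-starting every fit from the last converged result. Per-step recipe
#' overrides reproduce restricted-range protocols (e.g. `alpha` fixed to 4
#' and `sigma` bounded above by 0.08 for short-detector-distance drying
#' series). Non-converged fits are flagged, never dropped; the next fit
#' warm-starts from the last converged parameters.
#'
#' @param curves List of [curve1d()] objects in series order.
#' @param recipe A [fit_recipe()] for the first curve.
#' @param overrides Optional list with elements `fixed`, `lower`, `upper`
#'   merged into the recipe for every step (e.g.
#'   `list(fixed = "alpha", upper = c(sigma = 0.08))`).
#' @return List of [fit_curve()] results, one per curve.
#' @export
fit_series <- function(curves, recipe, overrides = NULL) {
  stopifnot(length(curves) >= 1L, inherits(recipe, "fit_recipe"))
  apply_overrides <- function(rec, init) {
    fit_recipe(structure(init, gaussian_enabled = rec$gaussian_enabled),
               fixed = union(rec$fixed, overrides$fixed),
               lower = {
                 lo <- rec$lower
                 if (!is.null(overrides$lower))
                   lo[names(overrides$lower)] <- overrides$lower
                 lo
               },
               upper = {
                 up <- rec$upper
                 if (!is.null(overrides$upper))
                   up[names(overrides$upper)] <- overrides$upper
                 up
               },
               rel_error = rec$rel_error, q_range = rec$q_range)
  }
  warm <- recipe$init
  out <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    rec_i <- apply_overrides(recipe, warm)
    out[[i]] <- fit_curve(curves[[i]], rec_i)
    if (out[[i]]$converged) warm <- out[[i]]$par
  }
  out
}
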