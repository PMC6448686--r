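#' Two-dimensional detector pattern with geometry
#'
#' Rectangular intensity array plus the geometry needed to map each pixel to
#' scattering vector magnitude q and azimuth phi. The exact relation
#' `q = 4 pi sin(theta) / lambda` with `2 theta = atan(r / distance)` is
#' used (no small-angle approximation). Azimuth phi is measured
#' counter-clockwise from the detector +x axis; with the fibre axis vertical
#' the equatorial maxima appear near phi = 0/180 degrees.
#'
#' @param intensity Numeric matrix of pixel intensities; rows index the
#'   detector y coordinate, columns x.
#' @param geometry Named list: `beam_center_x`, `beam_center_y` (pixels,
#'   x = column, y = row), `pixel_size` (mm), `distance` (sample-detector,
#'   mm), `wavelength` (angstrom).
#' @param mask Optional logical matrix, `TRUE` marking *excluded* pixels.
#' @return An object of class `"pattern2d"`.
#' @export
pattern2d <- function(intensity, geometry, mask = NULL) {
  stopifnot(is.matrix(intensity))
  need <- c("beam_center_x", "beam_center_y", "pixel_size", "distance",
            "wavelength")
  miss <- setdiff(need, names(geometry))
  if (length(miss))
    stop("missing geometry key(s): ", paste(miss, collapse = ", "))
  for (k in c("pixel_size", "distance", "wavelength"))
    if (geometry[[k]] <= 0) stop("geometry key '", k, "' must be > 0")
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
  } else {
    stopifnot(is.logical(mask), all(dim(mask) == dim(intensity)))
  }
  structure(list(intensity = intensity, geometry = geometry, mask = mask),
            class = "pattern2d")
}

#' @export
print.pattern2d <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("2D pattern: %d x %d pixels, %d masked\n",
              nrow(x$intensity), ncol(x$intensity), sum(x$mask)))
  cat(sprintf("  centre (%.2f, %.2f) px, pixel %.3g mm, distance %.4g mm, lambda %.3g A\n",
              g$beam_center_x, g$beam_center_y, g$pixel_size, g$distance,
              g$wavelength))
  invisible(x)
}

#' Per-pixel q and azimuth maps
#'
#' @param p A [pattern2d()].
#' @return List of two matrices, `q` (1/angstrom) and `phi` (degrees in
#'   `[0, 360)`), matching the intensity array.
#' @export
pixel_qphi <- function(p) {
  stopifnot(inherits(p, "pattern2d"))
  g <- p$geometry
  nr <- nrow(p$intensity); nc <- ncol(p$intensity)
  dx <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - g$beam_center_x) *
    g$pixel_size
  dy <- (matrix(seq_len(nr), nr, nc) - g$beam_center_y) * g$pixel_size
  r <- sqrt(dx^2 + dy^2)
  theta <- atan(r / g$distance) / 2
  q <- 4 * pi * sin(theta) / g$wavelength
  phi <- (atan2(dy, dx) * 180 / pi) %% 360
  list(q = q, phi = phi)
}

#' Azimuthal intensity profile over a q annulus
#'
#' Mean intensity in azimuthal bins over the annulus
#' `|q - q_center| <= q_halfwidth`, excluding masked pixels. Bins without
#' pixels are returned as `NA` (flagged missing).
#'
#' @param p A [pattern2d()].
#' @param q_center Annulus centre (1/angstrom).
#' @param q_halfwidth Annulus half-width (1/angstrom).
#' @param n_bins Number of azimuthal bins over `[0, 360)` (default 72).
#' @return An object of class `"azimuthal_profile"`: data frame with columns
#'   `phi` (bin centre, degrees) and `I`, plus q-annulus metadata.
#' @export
azimuthal_profile <- function(p, q_center, q_halfwidth, n_bins = 72L) {
  stopifnot(inherits(p, "pattern2d"))
  maps <- pixel_qphi(p)
  sel <- abs(maps$q - q_center) <= q_halfwidth & !p$mask
  if (!any(sel)) stop("empty annulus: no unmasked pixels in q range")
  edges <- seq(0, 360, length.out = n_bins + 1L)
  bin <- cut(maps$phi[sel], edges, include.lowest = TRUE, labels = FALSE)
  I <- as.numeric(tapply(p$intensity[sel], factor(bin, seq_len(n_bins)),
                         mean))
  structure(data.frame(phi = (edges[-1] + edges[-(n_bins + 1L)]) / 2, I = I),
            q_center = q_center, q_halfwidth = q_halfwidth,
            class = c("azimuthal_profile", "data.frame"))
}

# smallest angular distance on a 360-degree circle
.ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Fit the equatorial maximum of an azimuthal profile
#'
#' Least-squares fit of a pair of Gaussians separated by 180 degrees (fibre
#' symmetry) on a constant background anchored at the profile minimum:
#' `I(phi) = baseline + amp * [G(phi; phi0, sd) + G(phi; phi0 + 180, sd)]`.
#' The background slope defaults to zero (constant); the baseline is
#' initialised at the profile minimum and left free.
#'
#' @param profile An [azimuthal_profile()].
#' @param min_bins Minimum number of valid bins required (default 10).
#' @return List with `phi0` (degrees, reduced mod 180), `sd` (degrees),
#'   `baseline`, `amplitude`, and `converged`. A degenerate or failed fit is
#'   flagged `converged = FALSE` with `baseline = min(profile)`.
#' @export
fit_azimuthal_peak <- function(profile, min_bins = 10L) {
  ok <- is.finite(profile$I)
  if (sum(ok) < min_bins)
    stop("azimuthal profile has fewer than ", min_bins, " valid bins")
  phi <- profile$phi[ok]; I <- profile$I[ok]
  base0 <- min(I)
  amp0 <- max(I) - base0
  degenerate <- list(phi0 = NA_real_, sd = NA_real_, baseline = base0,
                     amplitude = 0, converged = FALSE)
  if (amp0 <= 0 || !is.finite(amp0)) return(degenerate)
  phi0_0 <- phi[which.max(I)] %% 180
  model <- function(par) {
    d1 <- .ang_diff(phi, par[["phi0"]])
    d2 <- .ang_diff(phi, par[["phi0"]] + 180)
    par[["baseline"]] + par[["amp"]] *
      (exp(-d1^2 / (2 * par[["sd"]]^2)) + exp(-d2^2 / (2 * par[["sd"]]^2)))
  }
  start <- c(phi0 = phi0_0, sd = 15, amp = amp0, baseline = base0)
  fit <- tryCatch(
    minpack.lm::nls.lm(start, lower = c(-90, 1, 0, 0),
                       upper = c(270, 90, Inf, Inf),
                       fn = function(par) I - model(par),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(degenerate)
  est <- fit$par
  # flag near-flat profiles where the fitted peak is indistinct
  if (est[["amp"]] < 3 * stats::sd(I - model(est)) && est[["amp"]] < 0.05 * base0)
    return(degenerate)
  list(phi0 = est[["phi0"]] %% 180, sd = est[["sd"]],
       baseline = est[["baseline"]], amplitude = est[["amp"]],
       converged = TRUE)
}

# default q-bin edges spanning the unmasked detector range
.default_q_grid <- function(p, n = 60L) {
  maps <- pixel_qphi(p)
  qs <- maps$q[!p$mask & maps$q > 0]
  seq(min(qs), max(qs), length.out = n + 1L)
}

#' Isotropic scattering component from azimuthal minima
#'
#' Approximates the isotropic contribution at each q as the minimum of the
#' azimuthal intensity profile over that q annulus (equatorial arcs vanish
#' away from the equator, leaving the non-oriented background).
#'
#' @param p A [pattern2d()].
#' @param q_grid Numeric vector of q bin *edges*; default spans the detector.
#' @param n_phi Azimuthal bins per annulus (default 36).
#' @return A [curve1d()] on the bin centres.
#' @export
isotropic_component <- function(p, q_grid = NULL, n_phi = 36L) {
  stopifnot(inherits(p, "pattern2d"))
  if (is.null(q_grid)) q_grid <- .default_q_grid(p)
  centers <- (q_grid[-1] + q_grid[-length(q_grid)]) / 2
  half <- diff(q_grid) / 2
  I <- vapply(seq_along(centers), function(i) {
    prof <- tryCatch(azimuthal_profile(p, centers[i], half[i], n_phi),
                     error = function(e) NULL)
    if (is.null(prof) || !any(is.finite(prof$I))) return(NA_real_)
    min(prof$I, na.rm = TRUE)
  }, numeric(1))
  keep <- is.finite(I)
  curve1d(centers[keep], I[keep],
          metadata = list(component = "isotropic", n_phi = n_phi))
}

#' Radial average over equatorial sectors
#'
#' Mean intensity per q bin over the two opposite sectors of the given
#' angular width centred at `phi0` and `phi0 + 180` degrees (fibre
#' symmetry); a single-sector mode is available. `width = 360` reproduces
#' the full azimuthal average.
#'
#' @param p A [pattern2d()].
#' @param phi0 Sector centre (degrees).
#' @param width Full sector width (degrees, default 25).
#' @param q_grid Numeric vector of q bin edges; default spans the detector.
#' @param both_sectors Average the two opposite sectors? Default `TRUE`.
#' @return A [curve1d()] with empirical standard errors as `sigma`.
#' @export
sector_average <- function(p, phi0, width = 25, q_grid = NULL,
                           both_sectors = TRUE) {
  stopifnot(inherits(p, "pattern2d"))
  if (is.null(q_grid)) q_grid <- .default_q_grid(p)
  maps <- pixel_qphi(p)
  insec <- .ang_diff(maps$phi, phi0) <= width / 2
  if (both_sectors)
    insec <- insec | .ang_diff(maps$phi, phi0 + 180) <= width / 2
  sel <- insec & !p$mask
  if (!any(sel)) stop("no unmasked pixels inside the sector")
  qv <- maps$q[sel]; Iv <- p$intensity[sel]
  bin <- cut(qv, q_grid, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(bin)
  bin <- factor(bin[keep], seq_len(length(q_grid) - 1L))
  n <- as.numeric(tapply(Iv[keep], bin, length))
  m <- as.numeric(tapply(Iv[keep], bin, mean))
  s <- as.numeric(tapply(Iv[keep], bin, stats::sd)) / sqrt(n)
  centers <- (q_grid[-1] + q_grid[-length(q_grid)]) / 2
  okbin <- !is.na(m)
  s[!is.na(s) & s <= 0] <- NA_real_
  curve1d(centers[okbin], m[okbin], s[okbin],
          metadata = list(phi0 = phi0, sector_width = width,
                          both_sectors = both_sectors,
                          convention = "phi CCW from detector +x"))
}

#' Equatorial excess intensity
#'
#' Pointwise subtraction of the isotropic component from a sector-averaged
#' curve on the sector's q grid; the isotropic curve is linearly
#' interpolated when the grids differ. Uncertainties are propagated in
#' quadrature where both curves carry them. Negative values are permitted
#' (noise) but a warning is raised if they are systematic.
#'
#' @param sector,iso [curve1d()] objects (sector average and isotropic
#'   component).
#' @return A [curve1d()] restricted to the q overlap.
#' @export
equatorial_excess <- function(sector, iso) {
  stopifnot(inherits(sector, "sas_curve"), inherits(iso, "sas_curve"))
  keep <- sector$q >= min(iso$q) & sector$q <= max(iso$q)
  q <- sector$q[keep]
  iso_I <- approx(iso$q, iso$I, xout = q)$y
  iso_s <- if (all(is.na(iso$sigma))) rep(NA_real_, length(q)) else
    approx(iso$q, iso$sigma, xout = q)$y
  I <- sector$I[keep] - iso_I
  s <- sqrt(ifelse(is.na(sector$sigma[keep]), 0, sector$sigma[keep]^2) +
              ifelse(is.na(iso_s), 0, iso_s^2))
  s[s <= 0] <- NA_real_
  if (mean(I < 0) > 0.5)
    warning("equatorial excess is negative over most of the q range; ",
            "check the sector centre and isotropic estimate")
  curve1d(q, I, s, metadata = c(curve_metadata(sector),
                                list(component = "equatorial_excess")))
}

#' Merge curves from different detector distances
#'
#' Scales successive curves onto the first by a least-squares factor on the
#' q overlap, concatenates, and optionally rebins onto a log-spaced q grid.
#'
#' @param curves List of [curve1d()] objects ordered by q range.
#' @param rebin Rebin the merged curve onto a log-spaced grid? Default
#'   `FALSE` (sorted concatenation, averaging duplicate q).
#' @param n_bins Number of log-spaced bins when `rebin = TRUE` (default 100).
#' @return A [curve1d()]; metadata records the scale factors applied.
#' @export
merge_curves <- function(curves, rebin = FALSE, n_bins = 100L) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "sas_curve")))
  scales <- rep(1, length(curves))
  base <- curves[[1]]
  qs <- base$q; Is <- base$I; ss <- base$sigma
  for (k in seq_along(curves)[-1]) {
    cur <- curves[[k]]
    lo <- max(min(qs), min(cur$q)); hi <- min(max(qs), max(cur$q))
    if (lo >= hi) stop("curves ", k - 1, " and ", k, " do not overlap in q")
    inref <- qs >= lo & qs <= hi
    ref_I <- Is[inref]
    cur_I <- approx(cur$q, cur$I, xout = qs[inref])$y
    # ref_I is already on the first curve's scale, so this factor maps the
    # raw curve k straight onto it
    scales[k] <- sum(ref_I * cur_I) / sum(cur_I^2)
    qs <- c(qs, cur$q); Is <- c(Is, scales[k] * cur$I)
    ss <- c(ss, scales[k] * cur$sigma)
  }
  o <- order(qs)
  qs <- qs[o]; Is <- Is[o]; ss <- ss[o]
  if (anyDuplicated(qs)) {
    # group on exact q equality (factor coercion would merge values that
    # differ only in the last bits)
    grp <- match(qs, unique(qs))
    Is <- as.numeric(tapply(Is, grp, mean))
    ss <- as.numeric(tapply(ss, grp, function(x)
      sqrt(sum(x^2)) / length(x)))
    qs <- unique(qs)
  }
  if (rebin) {
    edges <- exp(seq(log(min(qs)), log(max(qs)), length.out = n_bins + 1L))
    bin <- cut(qs, edges, include.lowest = TRUE, labels = FALSE)
    fb <- factor(bin, seq_len(n_bins))
    m <- as.numeric(tapply(Is, fb, mean))
    qa <- as.numeric(tapply(qs, fb, mean))
    sa <- as.numeric(tapply(ss, fb, function(x)
      if (all(is.na(x))) NA_real_ else sqrt(sum(x^2, na.rm = TRUE)) /
        sum(!is.na(x))))
    ok <- !is.na(m)
    qs <- qa[ok]; Is <- m[ok]; ss <- sa[ok]
  }
  ss[!is.na(ss) & ss <= 0] <- NA_real_
  curve1d(qs, Is, ss, metadata = list(merged = length(curves),
                                      scale_factors = scales,
                                      rebinned = rebin))
}
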