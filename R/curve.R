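#' One-dimensional scattering curve
#'
#' A (q, I, sigma) table with provenance metadata, the common currency of the
#' reduction, fitting and WAXS modules. q is in 1/angstrom and must be
#' strictly increasing; uncertainties, where present, must be positive.
#'
#' @param q Scattering vector magnitudes (1/angstrom), strictly increasing.
#' @param I Intensities.
#' @param sigma Optional 1-sd uncertainties (> 0 where finite; `NA` allowed).
#' @param metadata Named list of provenance fields (sector centre/width,
#'   generator truth, units, ...).
#' @return A data frame of class `"sas_curve"` with columns `q`, `I`,
#'   `sigma` and a `metadata` attribute.
#' @export
curve1d <- function(q, I, sigma = NULL, metadata = list()) {
  stopifnot(is.numeric(q), is.numeric(I), length(q) == length(I))
  if (length(q) && any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (is.null(sigma)) sigma <- rep(NA_real_, length(q))
  if (length(sigma) != length(q)) stop("sigma must match q in length")
  if (any(!is.na(sigma) & sigma <= 0)) stop("sigma must be > 0 where present")
  structure(data.frame(q = q, I = I, sigma = sigma),
            metadata = metadata,
            class = c("sas_curve", "data.frame"))
}

#' @export
print.sas_curve <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("1D scattering curve: %d points, q in [%.4g, %.4g] 1/A\n",
              nrow(x), min(x$q), max(x$q)))
  if (length(md)) {
    keys <- paste(names(md), collapse = ", ")
    cat("  metadata:", keys, "\n")
  }
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

curve_metadata <- function(curve) {
  md <- attr(curve, "metadata")
  if (is.null(md)) list() else md
}
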