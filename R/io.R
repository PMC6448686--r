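#' Read and write 1D curves as 3-column text
#'
#' The on-disk format is whitespace-separated `q I sigma` columns preceded
#' by `#`-prefixed header lines carrying `key: value` metadata. q is in
#' 1/angstrom unless the header declares `q_unit: 1/nm`, in which case it is
#' converted on read. A missing third column reads as unknown uncertainty.
#'
#' @param path File path.
#' @return `read_curve()`: a [curve1d()] with header metadata attached.
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  is_header <- grepl("^\\s*#", lines)
  md <- list()
  for (h in sub("^\\s*#\\s*", "", lines[is_header])) {
    m <- regmatches(h, regexec("^([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      md[[trimws(m[2])]] <- if (is.na(val)) m[3] else val
    }
  }
  body <- lines[!is_header & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path)
  fields <- strsplit(trimws(body), "\\s+")
  ncols <- lengths(fields)
  bad <- which(ncols != ncols[1] | ncols < 2)
  if (length(bad)) {
    lineno <- which(!is_header & nzchar(trimws(lines)))[bad[1]]
    stop("malformed row at line ", lineno, " of ", path)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = ncols[1], byrow = TRUE))
  if (anyNA(vals)) {
    badrow <- which(apply(is.na(vals), 1, any))[1]
    lineno <- which(!is_header & nzchar(trimws(lines)))[badrow]
    stop("malformed row at line ", lineno, " of ", path)
  }
  q <- vals[, 1]
  if (identical(md$q_unit, "1/nm")) {
    q <- q * 0.1                        # nm^-1 -> A^-1
    md$q_unit <- "1/A"
  }
  sigma <- if (ncol(vals) >= 3) vals[, 3] else NULL
  if (!is.null(sigma)) sigma[sigma <= 0] <- NA_real_
  curve1d(q, vals[, 2], sigma, metadata = md)
}

#' @rdname read_curve
#' @param curve A [curve1d()].
#' @param overwrite Refuse to overwrite an existing file unless `TRUE`.
#' @export
write_curve <- function(curve, path, overwrite = FALSE) {
  stopifnot(inherits(curve, "sas_curve"))
  if (file.exists(path) && !overwrite)
    stop("output file exists (use overwrite = TRUE): ", path)
  md <- curve_metadata(curve)
  md$q_unit <- "1/A"
  hdr <- vapply(names(md), function(k) {
    v <- md[[k]]
    sprintf("# %s: %s", k, paste(format(v, digits = 15), collapse = " "))
  }, character(1))
  body <- apply(cbind(curve$q, curve$I,
                      ifelse(is.na(curve$sigma), 0, curve$sigma)), 1,
                function(r) paste(format(r, digits = 12), collapse = "  "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 2D pattern from a plain-text matrix plus geometry sidecar
#'
#' The pattern is a whitespace-separated numeric matrix; the geometry
#' sidecar is `key = value` (or `key: value`) text with keys
#' `beam_center_x`, `beam_center_y`, `pixel_size`, `distance`,
#' `wavelength`. An optional mask file holds a 0/1 matrix of the same shape
#' (1 = excluded).
#'
#' @param path Matrix file path.
#' @param geometry_path Geometry sidecar path.
#' @param mask_path Optional mask file path.
#' @return `read_pattern()`: a [pattern2d()].
#' @export
read_pattern <- function(path, geometry_path, mask_path = NULL) {
  mat <- as.matrix(read.table(path))
  dimnames(mat) <- NULL
  geo <- read_keyvals(geometry_path)
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- as.matrix(read.table(mask_path)) != 0
    dimnames(mask) <- NULL
  }
  pattern2d(mat, geo, mask)
}

#' @rdname read_pattern
#' @param p A [pattern2d()].
#' @param overwrite Refuse to overwrite existing files unless `TRUE`.
#' @export
write_pattern <- function(p, path, geometry_path, overwrite = FALSE) {
  stopifnot(inherits(p, "pattern2d"))
  for (f in c(path, geometry_path))
    if (file.exists(f) && !overwrite)
      stop("output file exists (use overwrite = TRUE): ", f)
  write.table(p$intensity, path, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("%s = %s", names(p$geometry),
                     vapply(p$geometry, format, character(1), digits = 15)),
             geometry_path)
  invisible(path)
}

# parse 'key = value' / 'key: value' text into a named list, numbers where
# possible
read_keyvals <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([^=:]+?)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse line in ", path, ": ", ln)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[trimws(m[2])]] <- if (is.na(num)) val else num
  }
  out
}

#' Read a fit recipe from a key-value configuration file
#'
#' Lines are `key = value`, with dotted prefixes grouping sections:
#' `init.<param>` for starting values, `bounds.<param> = lo, hi`,
#' `fixed = p1, p2, ...`, plus optional `rel_error`, `q_min`, `q_max`, and
#' `gaussian_enabled = true/false`.
#'
#' @param path Configuration file path.
#' @return A [fit_recipe()].
#' @export
read_recipe <- function(path) {
  kv <- read_keyvals(path)
  init <- unlist(kv[grepl("^init\\.", names(kv))])
  names(init) <- sub("^init\\.", "", names(init))
  if (!length(init)) stop("recipe file declares no init.* values: ", path)
  fixed <- character()
  if (!is.null(kv$fixed))
    fixed <- trimws(strsplit(as.character(kv$fixed), ",")[[1]])
  lower <- NULL; upper <- NULL
  for (k in grep("^bounds\\.", names(kv), value = TRUE)) {
    pv <- as.numeric(trimws(strsplit(as.character(kv[[k]]), ",")[[1]]))
    if (length(pv) != 2 || anyNA(pv))
      stop("bounds must be 'lo, hi' in ", path, " for ", k)
    pn <- sub("^bounds\\.", "", k)
    lower <- c(lower, setNames(pv[1], pn))
    upper <- c(upper, setNames(pv[2], pn))
  }
  ge <- if (is.null(kv$gaussian_enabled)) "scale_B" %in% names(init) else
    tolower(as.character(kv$gaussian_enabled)) %in% c("true", "1", "yes")
  q_range <- NULL
  if (!is.null(kv$q_min) || !is.null(kv$q_max))
    q_range <- c(if (is.null(kv$q_min)) 0 else kv$q_min,
                 if (is.null(kv$q_max)) Inf else kv$q_max)
  fit_recipe(structure(init, gaussian_enabled = ge), fixed = fixed,
             lower = lower, upper = upper,
             rel_error = if (is.null(kv$rel_error)) 0.02 else kv$rel_error,
             q_range = q_range)
}

#' Serialize a fit result as a flat JSON record
#'
#' Writes the fitted parameters under their reporting names (lengths in nm)
#' together with uncertainties, fixed flags, reduced chi-squared and
#' convergence status.
#'
#' @param fit A `"sas_fit"` from [fit_curve()].
#' @param path Output path.
#' @param overwrite Refuse to overwrite unless `TRUE`.
#' @export
write_fit_json <- function(fit, path, overwrite = FALSE) {
  stopifnot(inherits(fit, "sas_fit"))
  if (file.exists(path) && !overwrite)
    stop("output file exists (use overwrite = TRUE): ", path)
  rec <- c(as.list(fit$par),
           list(stderr = as.list(fit$stderr[!is.na(fit$stderr)]),
                fixed = fit$fixed, redchi2 = fit$redchi2,
                converged = fit$converged, n_points = fit$n_points,
                gaussian_enabled = fit$gaussian_enabled))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
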