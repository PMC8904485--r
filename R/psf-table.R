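# Precomputed PSF error-curve lookup, cached per raster configuration.
# Fitting evaluates the blur error thousands of times; the image chain is
# only run once per (r, offset) node and interpolated in between.

.psf_cache <- new.env(parent = emptyenv())

#' Lookup table of PSF-induced orientation errors over a grid of r
#'
#' Evaluates [psf_error_curve()] on a regular grid of blur parameters at
#' the folded design offsets and returns an interpolation table used by
#' the fitting routines.  The table is cached in the package session by
#' its construction settings, so repeated calls are free.
#'
#' @param r_max grid extent: r runs from -r_max to r_max.
#' @param r_step grid step for r.
#' @param offsets folded offsets (degrees in [0, 90]) to tabulate.
#' @param spec,pitch,supersample raster settings, as in
#'   [psf_error_curve()].
#' @param verbose print a progress line while building.
#' @return object of class `psf_table`: list with `r_grid`, `offsets`,
#'   `errors` (length(r_grid) x length(offsets) matrix) and the raster
#'   settings.
#' @export
psf_curve_table <- function(r_max = 15, r_step = 0.1,
                            offsets = c(0, 22.5, 45, 67.5, 90),
                            spec = gabor_spec(), pitch = pixel_pitch(),
                            supersample = 8L, verbose = FALSE) {
  key <- paste(r_max, r_step, paste(offsets, collapse = ","),
               paste(unlist(spec), collapse = ","),
               signif(pitch, 12), supersample, sep = "|")
  hit <- get0(key, envir = .psf_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  r_grid <- seq(-r_max, r_max, by = r_step)
  # exact symmetry of the raster: a kernel with -r is the axis-swapped
  # kernel with +r, so error(-r, theta) = -error(r, 90 - theta); tabulate
  # r >= 0 and mirror (the symmetry itself is exercised by the direct
  # chain in the tests)
  pos <- r_grid[r_grid >= 0]
  errs_pos <- matrix(NA_real_, length(pos), length(offsets))
  for (i in seq_along(pos)) {
    errs_pos[i, ] <- psf_error_curve(pos[i], offsets, spec, pitch, supersample)
    if (verbose && i %% 25 == 0)
      message("psf_curve_table: ", i, "/", length(pos), " r values")
  }
  errors <- matrix(NA_real_, length(r_grid), length(offsets),
                   dimnames = list(NULL, offsets))
  for (i in seq_along(r_grid)) {
    ri <- r_grid[i]
    j <- match(round(abs(ri), 10), round(pos, 10))
    if (ri >= 0) {
      errors[i, ] <- errs_pos[j, ]
    } else {
      jm <- match(round(90 - offsets, 10), round(offsets, 10))
      if (any(is.na(jm)))
        stop("offsets must be closed under theta -> 90 - theta to mirror r < 0")
      errors[i, ] <- -errs_pos[j, jm]
    }
  }
  out <- structure(list(r_grid = r_grid, offsets = offsets, errors = errors,
                        spec = spec, pitch = pitch,
                        supersample = as.integer(supersample)),
                   class = "psf_table")
  assign(key, out, envir = .psf_cache)
  out
}

#' @export
print.psf_table <- function(x, ...) {
  cat("PSF error lookup:", length(x$r_grid), "r values in [",
      min(x$r_grid), ",", max(x$r_grid), "] x offsets {",
      paste(x$offsets, collapse = ", "), "} | f =", x$supersample, "\n")
  invisible(x)
}

#' Interpolate the PSF error curve at arbitrary r and signed offsets
#'
#' Linear interpolation in r of the tabulated folded curves; signed
#' offsets are folded using the antisymmetry error(-theta) = -error(theta)
#' that the axis-aligned kernel guarantees.
#'
#' @param table a `psf_table` from [psf_curve_table()].
#' @param r blur parameter (clamped to the table range).
#' @param offsets signed offsets in degrees; |offsets| must be tabulated.
#' @return numeric vector of interpolated errors.
#' @export
psf_error_interp <- function(table, r, offsets) {
  if (!inherits(table, "psf_table")) stop("expected a psf_table")
  folded <- abs(offsets)
  j <- match(round(folded, 10), round(table$offsets, 10))
  if (any(is.na(j)))
    stop("offsets not tabulated: ", paste(folded[is.na(j)], collapse = ", "))
  r <- min(max(r, min(table$r_grid)), max(table$r_grid))
  sgn <- ifelse(offsets < 0, -1, 1)
  vapply(seq_along(offsets), function(k) {
    sgn[k] * stats::approx(table$r_grid, table$errors[, j[k]], xout = r,
                           rule = 2)$y
  }, numeric(1))
}
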