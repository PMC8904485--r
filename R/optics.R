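#' Optical configuration of the simulated eye and display
#'
#' Physical constants of the reduced-eye geometry used by
#' [theoretical_r()] and to derive the angular size of one screen pixel.
#' Defaults describe the study display: a 2 mm pupil facing a bright
#' screen, 24 mm nodal distance, 0.50 mm screen pixels viewed at 600 mm.
#'
#' @param pupil_diameter pupil diameter L in mm.
#' @param nodal_distance distance N from nodal point to retina in mm.
#' @param screen_pixel_size physical size S of one screen pixel in mm.
#' @param viewing_distance viewing distance V in mm.
#' @return an object of class `optical_config`.
#' @export
#' @examples
#' cfg <- optical_config()
#' theoretical_r(cfg, cylinder = 1)
optical_config <- function(pupil_diameter = 2, nodal_distance = 24,
                           screen_pixel_size = 0.50, viewing_distance = 600) {
  vals <- c(pupil_diameter, nodal_distance, screen_pixel_size, viewing_distance)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("optical_config: all lengths must be finite and strictly positive")
  structure(list(L = pupil_diameter, N = nodal_distance,
                 S = screen_pixel_size, V = viewing_distance),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration (mm): pupil", x$L, "| nodal", x$N,
      "| pixel", x$S, "| distance", x$V, "\n")
  cat("Pixel pitch:", format(pixel_pitch(x), digits = 4), "deg\n")
  invisible(x)
}

#' Angular size of one screen pixel
#'
#' @param config an [optical_config()].
#' @return degrees of visual angle subtended by one screen pixel.
#' @export
pixel_pitch <- function(config = optical_config()) {
  atan(config$S / config$V) * 180 / pi
}

#' Theoretical blur parameter from cylindrical refractive error
#'
#' Closed-form prediction of the signed elliptical-blur parameter r (in
#' screen-pixel units) for a reduced astigmatic eye with cylindrical power
#' `cylinder` dioptres: r = B/P - 1, where P = N*S/V is the retinal size
#' of one pixel in the emmetropic eye, N_emme = L*N/(P+L) the emmetropic
#' focal distance, N_astig = 1/(1/N_emme + alpha) the focal distance along
#' the high-power meridian (alpha = cylinder/1000 in 1/mm), and
#' B = L*(N - N_astig)/N_astig the blur extent orthogonal to the
#' astigmatic axis.  r is 0 for an emmetropic eye and strictly increasing
#' in cylindrical power.
#'
#' @param config an [optical_config()].
#' @param cylinder cylindrical power in dioptres (>= 0), scalar or vector.
#' @return signed blur parameter(s) in screen-pixel units.
#' @export
#' @examples
#' theoretical_r(cylinder = c(0, 1, 4))
theoretical_r <- function(config = optical_config(), cylinder) {
  if (!inherits(config, "optical_config")) stop("config must be an optical_config")
  if (any(!is.finite(cylinder))) stop("cylinder must be finite")
  alpha <- cylinder / 1000                       # dioptre -> 1/mm
  P <- config$N * config$S / config$V
  N_emme <- config$L * config$N / (P + config$L)
  if (any(1 / N_emme + alpha <= 0))
    stop("cylinder power outside the model's domain")
  # B = L*(N - N_astig)/N_astig with 1/N_astig = 1/N_emme + alpha and
  # L*N/N_emme = P + L collapses to B = P + L*N*alpha, so B/P - 1 is
  # exactly L*N*alpha/P (zero at alpha = 0, linear and increasing)
  config$L * config$N * alpha / P
}

#' Discretized elliptical blur kernel
#'
#' Uniform-density elliptical point-spread kernel: constant inside the
#' ellipse (x/h)^2 + (y/v)^2 < 1, zero outside, normalized to unit sum.
#' The signed parameter r sets the semi-axes in screen-pixel units: for
#' r >= 0 the kernel is elongated orthogonally to the astigmatic axis
#' (semi-axes 1 along the axis, |r|+1 orthogonal); r < 0 swaps the axes;
#' r = 0 gives a circular kernel of unit semi-axes.  Semi-axes are scaled
#' by the supersample factor so the kernel acts on the supersampled
#' raster; cell weights are anti-aliased by subsampling each cell.
#'
#' @param r signed blur parameter in screen-pixel units.
#' @param supersample integer supersample factor f >= 1.
#' @param aa anti-aliasing subdivisions per cell side.
#' @return object of class `blur_kernel` with fields `r`, `supersample`,
#'   and `weights` (matrix; rows index the axis direction x, columns the
#'   orthogonal direction y).
#' @export
#' @examples
#' k <- build_kernel(5, supersample = 2)
#' sum(k$weights)  # 1
build_kernel <- function(r, supersample = 8L, aa = 4L) {
  if (!is.finite(r)) stop("r must be finite")
  f <- as.integer(supersample)
  if (f < 1L) stop("supersample must be >= 1")
  semi_y <- f * if (r >= 0) abs(r) + 1 else 1       # orthogonal to axis
  semi_x <- f * if (r >= 0) 1 else abs(r) + 1       # along axis
  nx <- ceiling(semi_x); ny <- ceiling(semi_y)
  xs <- -nx:nx; ys <- -ny:ny
  off <- (seq_len(aa) - (aa + 1) / 2) / aa
  w <- matrix(0, length(xs), length(ys))
  for (ox in off) for (oy in off) {
    xm <- matrix((xs + ox) / semi_x, length(xs), length(ys))
    ym <- matrix((ys + oy) / semi_y, length(xs), length(ys), byrow = TRUE)
    w <- w + (xm^2 + ym^2 < 1)
  }
  structure(list(r = r, supersample = f, weights = w / sum(w)),
            class = "blur_kernel")
}

#' @export
print.blur_kernel <- function(x, ...) {
  cat("Elliptical blur kernel: r =", x$r, "| supersample", x$supersample,
      "|", nrow(x$weights), "x", ncol(x$weights), "cells\n")
  invisible(x)
}

#' Gabor stimulus specification
#'
#' @param envelope_radius radius of the hard circular aperture in degrees.
#' @param spatial_frequency carrier frequency in cycles per degree.
#' @param michelson_contrast Michelson contrast in [0, 1].
#' @param phase carrier phase in degrees (0 or 180 for the two polarities).
#' @param background_luminance normalized background level in (0, 1).
#' @return object of class `gabor_spec`.
#' @export
gabor_spec <- function(envelope_radius = 0.25, spatial_frequency = 2,
                       michelson_contrast = 0.60, phase = 0,
                       background_luminance = 0.5) {
  if (michelson_contrast < 0 || michelson_contrast > 1)
    stop("michelson_contrast must be in [0, 1]")
  if (envelope_radius <= 0 || spatial_frequency <= 0)
    stop("envelope_radius and spatial_frequency must be positive")
  structure(list(envelope_radius = envelope_radius,
                 spatial_frequency = spatial_frequency,
                 michelson_contrast = michelson_contrast,
                 phase = phase,
                 background_luminance = background_luminance),
            class = "gabor_spec")
}

#' Render a Gabor stimulus on the supersampled raster
#'
#' Sinusoidal carrier under a hard circular aperture on a uniform
#' background.  The raster window is twice the envelope diameter per
#' side; the carrier's zero-crossing passes through the image centre
#' (sine phase), which is the luminance boundary that
#' [decode_orientation()] reads out.  Orientations are offsets from the
#' astigmatic axis, which is rendered horizontal.
#'
#' @param orientation offset from the astigmatic axis in degrees,
#'   in (-90, 90].
#' @param spec a [gabor_spec()].
#' @param pitch degrees of visual angle per screen pixel (see
#'   [pixel_pitch()]).
#' @param supersample integer supersample factor f >= 1.
#' @param window raster half-width in degrees; defaults to twice the
#'   envelope radius (a window of twice the envelope diameter).
#' @return object of class `retinal_image`: list with `luminance`
#'   (matrix in [0, 1]; rows index x along the axis, columns y), `pitch`,
#'   `supersample`, and the generating `spec`.
#' @export
render_gabor <- function(orientation, spec = gabor_spec(),
                         pitch = pixel_pitch(), supersample = 8L,
                         window = 2 * spec$envelope_radius) {
  if (pitch <= 0) stop("pitch must be positive")
  f <- as.integer(supersample)
  if (f < 1L) stop("supersample must be >= 1")
  step <- pitch / f
  half <- window                            # window half-width, degrees
  if (half < spec$envelope_radius)
    stop("envelope larger than the raster window")
  n <- ceiling(half / step)
  ax <- (-n:n) * step
  m <- 2L * n + 1L
  x <- matrix(ax, m, m)                     # rows: x (astigmatic axis)
  y <- matrix(ax, m, m, byrow = TRUE)       # cols: y (orthogonal)
  th <- orientation * pi / 180
  u <- -x * sin(th) + y * cos(th)           # signed distance across stripes
  bg <- spec$background_luminance
  amp <- spec$michelson_contrast * bg
  img <- bg + amp * sin(2 * pi * spec$spatial_frequency * u +
                          spec$phase * pi / 180)
  img[x^2 + y^2 > spec$envelope_radius^2] <- bg
  structure(list(luminance = pmin(pmax(img, 0), 1), pitch = pitch,
                 supersample = f, spec = spec),
            class = "retinal_image")
}

#' @export
print.retinal_image <- function(x, ...) {
  cat("Retinal image:", nrow(x$luminance), "x", ncol(x$luminance),
      "supersampled pixels | pitch", format(x$pitch, digits = 4),
      "deg / screen px | f =", x$supersample, "\n")
  invisible(x)
}

#' Convolve a retinal image with a blur kernel
#'
#' Two-dimensional convolution with same-size output.  The image is
#' padded with the background luminance so the stimulus behaves as if
#' embedded in the uniform gray field it was presented on; since the
#' kernel sums to one, mean luminance is preserved.
#'
#' @param img a `retinal_image` from [render_gabor()].
#' @param kernel a `blur_kernel` from [build_kernel()].
#' @return a blurred `retinal_image`.
#' @export
blur_image <- function(img, kernel) {
  if (!inherits(img, "retinal_image") || !inherits(kernel, "blur_kernel"))
    stop("blur_image expects a retinal_image and a blur_kernel")
  if (img$supersample != kernel$supersample)
    stop("supersample factors of image and kernel differ")
  k <- kernel$weights
  bg <- img$spec$background_luminance
  px <- nrow(k) %/% 2 + 1L
  py <- ncol(k) %/% 2 + 1L
  a <- img$luminance
  big <- matrix(bg, nrow(a) + 2L * px, ncol(a) + 2L * py)
  big[px + seq_len(nrow(a)), py + seq_len(ncol(a))] <- a
  out <- EBImage::filter2(big, k, boundary = bg)
  img$luminance <- out[px + seq_len(nrow(a)), py + seq_len(ncol(a))]
  img
}

#' Decode the orientation of the central luminance boundary
#'
#' Reads out the stimulus orientation the way an edge detector would:
#' the image is referenced to the background luminance, the central
#' bright/dark interface is localized as the set of sub-pixel
#' zero-crossing points between neighbouring pixels of opposite sign
#' (plus pixels lying exactly on the boundary), restricted to the central
#' part of the envelope, and the orientation is the principal axis of the
#' coordinate covariance of those points.
#'
#' @param img a `retinal_image`.
#' @param central_fraction fraction of the envelope radius within which
#'   boundary points are collected.
#' @return decoded orientation offset in degrees, in (-90, 90].
#' @export
decode_orientation <- function(img, central_fraction = 0.8) {
  if (!inherits(img, "retinal_image")) stop("expected a retinal_image")
  a <- img$luminance
  bg <- img$spec$background_luminance
  step <- img$pitch / img$supersample
  n <- (nrow(a) - 1L) / 2L
  ax <- (-n:n) * step
  d <- a - bg
  tol <- 1e-12
  if (max(d) - min(d) < tol)
    stop("decode failure: image is uniform, no luminance boundary")
  px <- numeric(0); py <- numeric(0)
  zz <- abs(d) < tol                         # points exactly on the boundary
  if (any(zz)) {
    idx <- which(zz, arr.ind = TRUE)
    px <- ax[idx[, 1]]; py <- ax[idx[, 2]]
  }
  A <- d[-nrow(d), ]; B <- d[-1, ]           # sign changes along x
  sel <- A * B < -tol^2
  if (any(sel)) {
    idx <- which(sel, arr.ind = TRUE)
    tt <- A[sel] / (A[sel] - B[sel])
    px <- c(px, ax[idx[, 1]] + tt * step)
    py <- c(py, ax[idx[, 2]])
  }
  A <- d[, -ncol(d)]; B <- d[, -1]           # sign changes along y
  sel <- A * B < -tol^2
  if (any(sel)) {
    idx <- which(sel, arr.ind = TRUE)
    tt <- A[sel] / (A[sel] - B[sel])
    px <- c(px, ax[idx[, 1]])
    py <- c(py, ax[idx[, 2]] + tt * step)
  }
  rmax <- central_fraction * img$spec$envelope_radius
  keep <- px^2 + py^2 <= rmax^2
  if (sum(keep) < 2L)
    stop("decode failure: no luminance boundary detected near the centre")
  xs <- px[keep] - mean(px[keep])
  ys <- py[keep] - mean(py[keep])
  cc <- cbind(c(sum(xs * xs), c(sum(xs * ys))),
              c(sum(xs * ys), sum(ys * ys)))
  ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  wrap_offset(atan2(ev[2], ev[1]) * 180 / pi)
}

#' Per-offset orientation errors induced by elliptical blur
#'
#' Runs the full render -> blur -> decode chain at each stimulus offset
#' and returns the signed decoding error, the optical component of the
#' perceptual bias: error(theta) = decode(blur(render(theta))) - theta,
#' wrapped to (-90, 90].  Positive errors at positive offsets mean the
#' decoded orientation is pushed away from the astigmatic axis.
#'
#' @param r signed blur parameter.
#' @param offsets stimulus offsets in degrees, each in (-90, 90].
#' @param spec a [gabor_spec()].
#' @param pitch degrees per screen pixel.
#' @param supersample supersample factor.
#' @return named numeric vector of errors (degrees), one per offset.
#' @export
#' @examples
#' \donttest{
#' psf_error_curve(3, c(-45, 0, 45), supersample = 4)
#' }
psf_error_curve <- function(r, offsets = c(0, 22.5, 45, 67.5, 90),
                            spec = gabor_spec(), pitch = pixel_pitch(),
                            supersample = 8L) {
  kernel <- build_kernel(r, supersample)
  err <- vapply(offsets, function(th) {
    img <- blur_image(render_gabor(th, spec, pitch, supersample), kernel)
    wrap_offset(decode_orientation(img) - th)
  }, numeric(1))
  names(err) <- offsets
  err
}
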