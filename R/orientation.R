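#' Wrap an orientation difference to (-90, 90]
#'
#' Orientations have period 180 degrees; differences between them live on
#' the half-open interval (-90, 90].  All model-facing quantities in this
#' package (offsets from the astigmatic axis, perceptual errors) use this
#' convention.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector wrapped to (-90, 90].
#' @export
#' @examples
#' wrap_offset(c(0, 91, -95, 180, 269))
wrap_offset <- function(x) {
  y <- x %% 180
  y[y > 90] <- y[y > 90] - 180
  y
}

#' Wrap an absolute orientation to [0, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector wrapped to [0, 180).
#' @export
wrap_orientation <- function(x) x %% 180

#' Circular mean of orientation errors (period 180)
#'
#' Computed on angle-doubled values, the standard device for axial data:
#' the errors are doubled, averaged as directions on the circle, and the
#' mean direction is halved.
#'
#' @param x numeric vector of errors in degrees, each in (-90, 90].
#' @return scalar mean in degrees in (-90, 90].
#' @export
circ_mean_orient <- function(x) {
  if (length(x) == 0L) stop("empty input")
  a <- 2 * x * pi / 180
  wrap_offset(atan2(mean(sin(a)), mean(cos(a))) * 180 / pi / 2)
}

#' Circular standard deviation of orientation errors (period 180)
#'
#' Angle-doubled circular SD, halved back to the orientation scale:
#' sqrt(-2 log Rbar) / 2 converted to degrees, where Rbar is the mean
#' resultant length of the doubled angles.  For errors much smaller than
#' 90 degrees this closely approximates the linear SD.
#'
#' @param x numeric vector of errors in degrees.
#' @return scalar SD in degrees (>= 0).
#' @export
circ_sd_orient <- function(x) {
  if (length(x) == 0L) stop("empty input")
  a <- 2 * x * pi / 180
  rbar <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  rbar <- min(rbar, 1)
  sqrt(-2 * log(rbar)) / 2 * 180 / pi
}

# circular distance between orientations, period 180, result in [0, 90]
orient_dist <- function(a, b) abs(wrap_offset(a - b))
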