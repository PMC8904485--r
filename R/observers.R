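# Neural observer models predicting perceptual errors beyond the optics:
# orientation-specific adaptation (gain-modulated population code) and a
# Gaussian Bayesian prior-integration observer.  All orientations are
# offsets from the astigmatic axis (degrees, period 180); the adapted /
# prior orientation is 90, orthogonal to the axis.

#' Gain profile of the adapted population
#'
#' Multiplicative response gain over preferred orientations after
#' long-term adaptation: gain(theta) = 1 - a * exp(-d(theta, 90)^2 /
#' (2 * (3 * sigma_m)^2)), with d the circular distance (period 180).
#' The Gaussian dip is centred on the orientation orthogonal to the
#' astigmatic axis and is three times broader than the measurement
#' tuning.  a = 0 leaves the gain flat at 1; a = 1 silences the adapted
#' orientation; negative a describes a gain increase.
#'
#' @param a gain-loss amplitude (dimensionless; the fitted value times
#'   100 is the percent gain loss).
#' @param sigma_m measurement tuning SD in degrees (> 0).
#' @param grid preferred orientations in degrees.
#' @param adapted adapted orientation (default 90).
#' @return numeric vector of gains over `grid`.
#' @export
gain_profile <- function(a, sigma_m, grid, adapted = 90) {
  if (sigma_m <= 0) stop("sigma_m must be positive")
  d <- orient_dist(grid, adapted)
  1 - a * exp(-d^2 / (2 * (3 * sigma_m)^2))
}

# default preferred/stimulus orientation grid: 0.5 deg over (-90, 90]
orientation_grid <- function(step = 0.5) seq(-90 + step, 90, by = step)

#' Perceived orientation read out from the gain-modulated population
#'
#' Each measurement (preferred orientation) responds to the stimulus with
#' a Gaussian tuning profile of SD `sigma_m` (period 180) scaled by its
#' adapted gain.  The population response over preferred orientations is
#' normalized to a probability distribution and its mean is the perceived
#' orientation.  The mean is taken on the grid re-centred at the stimulus
#' so the 180-degree wrap cannot split the (unimodal, local) distribution.
#'
#' @param stimulus stimulus orientation offset in degrees.
#' @param a gain-loss amplitude.
#' @param sigma_m measurement tuning SD in degrees.
#' @param step orientation grid step in degrees.
#' @param adapted adapted orientation (default 90).
#' @return perceived orientation offset in degrees, in (-90, 90].
#' @export
population_readout <- function(stimulus, a, sigma_m, step = 0.5,
                               adapted = 90) {
  if (sigma_m <= 0) stop("sigma_m must be positive")
  grid <- orientation_grid(step)
  # preferred orientations unwrapped onto stimulus +- 90
  pref <- stimulus + wrap_offset(grid - stimulus)
  resp <- exp(-orient_dist(grid, stimulus)^2 / (2 * sigma_m^2)) *
    gain_profile(a, sigma_m, grid, adapted)
  if (all(resp <= 0)) stop("population response is not positive")
  p <- resp / sum(resp)
  wrap_offset(sum(p * pref))
}

#' Neural error curve of the adaptation model
#'
#' error(theta) = readout(theta) - theta.  With a > 0 the curve repels
#' perceived orientations away from the adapted orientation (negative
#' just below 90), is odd about 90, and vanishes at 0 and 90.
#'
#' @param a gain-loss amplitude.
#' @param sigma_m measurement tuning SD in degrees.
#' @param offsets stimulus offsets in degrees.
#' @param step grid step in degrees.
#' @return named numeric vector of neural errors (degrees).
#' @export
#' @examples
#' adaptation_error_curve(0.3, 8, c(0, 22.5, 45, 67.5, 90))
adaptation_error_curve <- function(a, sigma_m,
                                   offsets = c(0, 22.5, 45, 67.5, 90),
                                   step = 0.5) {
  err <- vapply(offsets, function(th)
    wrap_offset(population_readout(th, a, sigma_m, step) - th), numeric(1))
  names(err) <- offsets
  err
}

#' Bayesian percept: precision-weighted fusion of likelihood and prior
#'
#' mu_percept = (mu_lik / sigma_lik^2 + mu_pri / sigma_pri^2) /
#' (1 / sigma_lik^2 + 1 / sigma_pri^2), evaluated in the circular frame
#' re-centred on the likelihood mean (the prior mean enters through its
#' wrapped difference from the stimulus).
#'
#' @param mu_lik likelihood mean (stimulus orientation offset), degrees.
#' @param sigma_lik likelihood SD in degrees (> 0).
#' @param mu_pri prior mean in degrees (default 90, orthogonal to the
#'   astigmatic axis).
#' @param sigma_pri prior SD in degrees (> 0).
#' @return perceived orientation offset in degrees, in (-90, 90].
#' @export
#' @examples
#' bayes_percept(67.5, 5, 90, 10)   # 72
bayes_percept <- function(mu_lik, sigma_lik, mu_pri = 90, sigma_pri) {
  if (sigma_lik <= 0 || sigma_pri <= 0) stop("SDs must be positive")
  d <- wrap_offset(mu_pri - mu_lik)
  # antipodal tie: a prior 90 deg away (period 180) pulls equally in both
  # circular directions, so its net attraction cancels
  d[abs(d) == 90] <- 0
  w <- (1 / sigma_pri^2) / (1 / sigma_lik^2 + 1 / sigma_pri^2)
  wrap_offset(mu_lik + w * d)
}

#' Neural error curve of the Bayesian model
#'
#' error(theta) = bayes_percept(theta) - theta: attraction toward the
#' prior mean at 90, the opposite sign to the adaptation model.
#'
#' @param sigma_pri prior SD in degrees.
#' @param sigma_lik likelihood SD in degrees (the behavioral SD).
#' @param offsets stimulus offsets in degrees.
#' @param mu_pri prior mean (default 90).
#' @return named numeric vector of neural errors (degrees).
#' @export
bayes_error_curve <- function(sigma_pri, sigma_lik,
                              offsets = c(0, 22.5, 45, 67.5, 90),
                              mu_pri = 90) {
  err <- vapply(offsets, function(th)
    wrap_offset(bayes_percept(th, sigma_lik, mu_pri, sigma_pri) - th),
    numeric(1))
  names(err) <- offsets
  err
}

#' Combined optical + neural prediction for both vision states
#'
#' Retinal distortion and neural modification are assumed additive.  The
#' astigmatic-state prediction is the PSF error curve at blur r plus the
#' neural error curve; the emmetropic-state prediction is the neural
#' curve alone (no optical distortion once refraction is corrected).  The
#' neural curve is common to both states: the adaptation (or prior) is a
#' long-term property of the observer, which is what lets it produce the
#' inverse bias seen with full correction.
#'
#' @param model "adapt" or "bayes".
#' @param r blur parameter for the astigmatic state.
#' @param neural_par gain-loss a (adapt) or prior SD sigma_pri (bayes).
#' @param sigma_m measurement / likelihood SD in degrees.
#' @param offsets stimulus offsets (signed or folded) in degrees.
#' @param psf either a `psf_table` (interpolated; used in fitting) or
#'   NULL to run the image chain directly.
#' @param step adaptation readout grid step.
#' @param supersample raster supersample factor when `psf` is NULL.
#' @return object of class `observer_prediction`: list with `offsets`,
#'   `retinal` (astigmatic-state optical errors), `neural`, and the
#'   per-state predictions `astigmatic` = retinal + neural and
#'   `emmetropic` = neural.
#' @export
combined_prediction <- function(model = c("adapt", "bayes"), r, neural_par,
                                sigma_m, offsets = c(0, 22.5, 45, 67.5, 90),
                                psf = NULL, step = 0.5, supersample = 8L) {
  model <- match.arg(model)
  retinal <- if (is.null(psf)) {
    unname(psf_error_curve(r, offsets, supersample = supersample))
  } else {
    psf_error_interp(psf, r, offsets)
  }
  neural <- if (model == "adapt") {
    sgn <- ifelse(offsets < 0, -1, 1)
    sgn * unname(adaptation_error_curve(neural_par, sigma_m, abs(offsets),
                                        step))
  } else {
    vapply(offsets, function(th)
      wrap_offset(bayes_percept(th, sigma_m, 90, neural_par) - th),
      numeric(1))
  }
  structure(list(model = model, offsets = offsets, retinal = retinal,
                 neural = neural,
                 astigmatic = retinal + neural,
                 emmetropic = neural),
            class = "observer_prediction")
}

#' @export
print.observer_prediction <- function(x, digits = 3, ...) {
  cat("Observer prediction (", x$model, " model), errors in deg\n", sep = "")
  print(data.frame(offset = x$offsets,
                   retinal = round(x$retinal, digits),
                   neural = round(x$neural, digits),
                   astigmatic = round(x$astigmatic, digits),
                   emmetropic = round(x$emmetropic, digits)),
        row.names = FALSE)
  invisible(x)
}
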