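#' Signed perceptual error of one or more trials
#'
#' Circular difference reported - stimulus, wrapped to (-90, 90].
#'
#' @param stimulus stimulus orientation(s) in degrees, [0, 180).
#' @param reported reported orientation(s) in degrees, [0, 180).
#' @return signed error(s) in degrees in (-90, 90].
#' @export
#' @examples
#' signed_error(179, 1)   # +2, wrapping across 180
#' signed_error(45, 40)   # -5
signed_error <- function(stimulus, reported) {
  if (any(stimulus < 0 | stimulus >= 180 | reported < 0 | reported >= 180))
    stop("orientations must lie in [0, 180)")
  wrap_offset(reported - stimulus)
}

#' Remove an eye's constant clockwise/counter-clockwise report bias
#'
#' Subtracts the circular mean of all errors (per eye and condition) from
#' each error, so the debiased errors have circular mean zero.
#'
#' @param errors numeric vector of signed errors in degrees.
#' @return debiased errors, wrapped to (-90, 90].
#' @export
debias_errors <- function(errors) {
  if (length(errors) == 0L) stop("debias_errors: empty input")
  wrap_offset(errors - circ_mean_orient(errors))
}

# offset of a trial's stimulus from its astigmatic axis, in (-90, 90]
stimulus_offset <- function(stimulus, axis) wrap_offset(stimulus - axis)

#' Fold signed offsets onto [0, 90] and average the errors
#'
#' Implements the study's folding rule in offset coordinates: trials at
#' mirror-image offsets -theta have their error signs inverted and are
#' merged with the +theta trials, so that a positive folded bias always
#' means "repelled from the astigmatic axis".  Means are taken per folded
#' offset magnitude.
#'
#' @param offsets signed stimulus offsets in degrees, drawn from the
#'   eight-point design (0, +-22.5, +-45, +-67.5, 90).
#' @param errors debiased signed errors, same length.
#' @param design_offsets folded offset magnitudes defining the design.
#' @return object of class `bias_profile`: list with `offsets` (folded),
#'   `mean_bias` (NA where no trials), and `n` per offset.
#' @export
fold_and_collapse <- function(offsets, errors,
                              design_offsets = c(0, 22.5, 45, 67.5, 90)) {
  if (length(offsets) != length(errors))
    stop("offsets and errors must have the same length")
  folded <- abs(offsets)
  bad <- is.na(match(round(folded, 6), round(design_offsets, 6)))
  if (any(bad))
    stop("offsets outside the design at trials: ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  signed <- ifelse(offsets < 0, -errors, errors)
  grp <- factor(round(folded, 6), levels = round(design_offsets, 6))
  mean_bias <- as.numeric(tapply(signed, grp, mean))
  n <- as.integer(table(grp))
  structure(list(offsets = design_offsets, mean_bias = mean_bias, n = n),
            class = "bias_profile")
}

#' @export
print.bias_profile <- function(x, digits = 3, ...) {
  cat("Folded bias profile (deg; + = repelled from the astigmatic axis)\n")
  print(data.frame(offset = x$offsets,
                   mean_bias = round(x$mean_bias, digits),
                   n = x$n), row.names = FALSE)
  invisible(x)
}

#' @export
plot.bias_profile <- function(x, ...) {
  graphics::plot(x$offsets, x$mean_bias, type = "b", pch = 16,
                 xlab = "offset from astigmatic axis (deg)",
                 ylab = "bias (deg)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Bias profile of one eye and vision state from trial records
#'
#' Convenience wrapper: computes signed errors, debiases them (per eye
#' and state, as the preprocessing prescribes), and folds across the
#' axis.
#'
#' @param trials a trial data frame (see [read_trials()]) for a single
#'   eye and vision state.
#' @param design_offsets folded offsets of the design.
#' @return a `bias_profile`.
#' @export
bias_profile <- function(trials, design_offsets = c(0, 22.5, 45, 67.5, 90)) {
  err <- debias_errors(signed_error(trials$stimulus_orientation,
                                    trials$reported_orientation))
  off <- stimulus_offset(trials$stimulus_orientation, trials$astigmatic_axis)
  fold_and_collapse(off, err, design_offsets)
}

#' Response variability of an eye across vision states
#'
#' Circular SDs of debiased errors, overall and per folded offset, for
#' the emmetropic and astigmatic states, and the per-offset percent
#' change of SD under astigmatic viewing:
#' 100 * (SD_astig - SD_emme) / SD_emme.  Linear SDs are reported
#' alongside for reference.
#'
#' @param trials trial data frame for one eye containing both vision
#'   states (`vision_state` of "emmetropic" and "astigmatic").
#' @param design_offsets folded offsets of the design.
#' @return object of class `variability_profile`: list with `offsets`,
#'   per-state `sd_overall`, `sd_per_offset`, `sd_linear`, and
#'   `percent_change` (NA, with a warning, where SD_emme is 0).
#' @export
variability_profile <- function(trials,
                                design_offsets = c(0, 22.5, 45, 67.5, 90)) {
  states <- c("emmetropic", "astigmatic")
  if (!all(states %in% trials$vision_state))
    stop("variability_profile needs both vision states")
  per_state <- lapply(states, function(st) {
    tr <- trials[trials$vision_state == st, , drop = FALSE]
    err <- debias_errors(signed_error(tr$stimulus_orientation,
                                      tr$reported_orientation))
    off <- stimulus_offset(tr$stimulus_orientation, tr$astigmatic_axis)
    # fold with the same sign-flip rule as the bias profile, so the +-theta
    # sub-populations share one mean and the bias does not inflate the SD
    err <- ifelse(off < 0, -err, err)
    grp <- factor(round(abs(off), 6), levels = round(design_offsets, 6))
    list(overall = circ_sd_orient(err),
         per_offset = as.numeric(tapply(err, grp, circ_sd_orient)),
         linear = as.numeric(tapply(err, grp, stats::sd)))
  })
  names(per_state) <- states
  sd_e <- per_state$emmetropic$per_offset
  sd_a <- per_state$astigmatic$per_offset
  pct <- 100 * (sd_a - sd_e) / sd_e
  if (any(!is.na(sd_e) & sd_e == 0)) {
    warning("zero emmetropic SD at some offsets; percent change undefined")
    pct[sd_e == 0] <- NA_real_
  }
  structure(list(offsets = design_offsets,
                 sd_overall = c(emmetropic = per_state$emmetropic$overall,
                                astigmatic = per_state$astigmatic$overall),
                 sd_per_offset = cbind(emmetropic = sd_e, astigmatic = sd_a),
                 sd_linear = cbind(emmetropic = per_state$emmetropic$linear,
                                   astigmatic = per_state$astigmatic$linear),
                 percent_change = pct),
            class = "variability_profile")
}

#' @export
print.variability_profile <- function(x, digits = 3, ...) {
  cat("Response variability (circular SD, deg)\n")
  cat("Overall: emmetropic", round(x$sd_overall[1], digits),
      "| astigmatic", round(x$sd_overall[2], digits), "\n")
  print(data.frame(offset = x$offsets,
                   sd_emme = round(x$sd_per_offset[, 1], digits),
                   sd_astig = round(x$sd_per_offset[, 2], digits),
                   pct_change = round(x$percent_change, 1)),
        row.names = FALSE)
  invisible(x)
}
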