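# Compensation analysis: how far each chronically astigmatic eye's fitted
# blur falls below the control group's blur-vs-dioptre regression line.

#' Compensation of chronic eyes relative to the control regression
#'
#' Fits a least-squares line of the control eyes' fitted blur r on
#' cylinder power (dioptre), averages the line over seeded bootstrap
#' resamples (control eyes resampled with replacement as whole units,
#' keeping all of an eye's dioptre conditions together), and computes
#' each chronic eye's compensation as the bootstrap-mean line evaluated
#' at its dioptre minus its own fitted r.  Positive compensation means
#' the chronic eye's effective blur sits below the control line.
#'
#' @param chronic data frame with columns `eye_id`, `cylinder_power`,
#'   `r` (fitted blur) for the chronic eyes.
#' @param control data frame with columns `eye_id`, `cylinder_power`,
#'   `r` for the control eyes (one row per eye x lens condition).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @return object of class `compensation_result`: list with `slope`,
#'   `intercept` (point estimates), `boot_slope`, `boot_intercept`
#'   (bootstrap means), `band` (2.5/97.5 percentile lines over a dioptre
#'   grid), and `per_eye` (chronic eye table with `compensation`).
#' @export
compensation_analysis <- function(chronic, control, n_boot = 1000L,
                                  seed = 1L) {
  need <- c("eye_id", "cylinder_power", "r")
  if (!all(need %in% names(chronic)) || !all(need %in% names(control)))
    stop("chronic and control need columns eye_id, cylinder_power, r")
  if (length(unique(control$cylinder_power)) < 2)
    stop("control design degenerate: need >= 2 distinct dioptres")
  fit <- stats::lm(r ~ cylinder_power, data = control)
  co <- stats::coef(fit)
  eyes <- unique(control$eye_id)
  grid <- seq(min(control$cylinder_power), max(control$cylinder_power),
              length.out = 41L)
  boot <- with_seed(seed, function() {
    t(vapply(seq_len(n_boot), function(b) {
      take <- sample(eyes, length(eyes), replace = TRUE)
      dat <- do.call(rbind, lapply(take, function(e)
        control[control$eye_id == e, , drop = FALSE]))
      if (length(unique(dat$cylinder_power)) < 2) return(c(NA_real_, NA_real_))
      stats::coef(stats::lm(r ~ cylinder_power, data = dat))
    }, numeric(2)))
  })
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  bi <- mean(boot[, 1]); bs <- mean(boot[, 2])
  lines <- boot[, 1] + outer(boot[, 2], grid)
  band <- apply(lines, 2, stats::quantile, probs = c(0.025, 0.975))
  per_eye <- chronic[, need]
  per_eye$line_r <- bi + bs * per_eye$cylinder_power
  per_eye$compensation <- per_eye$line_r - per_eye$r
  structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                 boot_intercept = bi, boot_slope = bs,
                 n_boot = nrow(boot), grid = grid, band = band,
                 per_eye = per_eye, seed = seed),
            class = "compensation_result")
}

#' @export
print.compensation_result <- function(x, digits = 3, ...) {
  cat("Compensation analysis (control line r ~ dioptre)\n")
  cat("Point estimate: intercept", round(x$intercept, digits), "slope",
      round(x$slope, digits), "\n")
  cat("Bootstrap mean (", x$n_boot, " reps): intercept ",
      round(x$boot_intercept, digits), " slope ",
      round(x$boot_slope, digits), "\n", sep = "")
  cat("Mean chronic compensation:",
      round(mean(x$per_eye$compensation), digits), "deg-equivalent r units\n")
  invisible(x)
}

#' @export
plot.compensation_result <- function(x, ...) {
  pe <- x$per_eye
  graphics::plot(pe$cylinder_power, pe$r, pch = 16, col = 2,
                 xlab = "cylinder power (D)", ylab = "fitted r", ...)
  graphics::abline(x$boot_intercept, x$boot_slope)
  graphics::lines(x$grid, x$band[1, ], lty = 2)
  graphics::lines(x$grid, x$band[2, ], lty = 2)
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties, as used to relate fitted
#' quantities (compensation vs residual blur, gain loss, cylinder
#' power).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return correlation coefficient in [-1, 1].
#' @export
#' @examples
#' rank_correlation(1:4, c(2, 1, 4, 3))   # 0.6
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for constant input")
  stats::cor(x, y, method = "spearman")
}
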