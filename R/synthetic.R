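# Synthetic behavioral-data generator: trial-level cohorts with the
# statistical structure the analysis assumes and known ground truth, so
# every downstream stage is testable without human data.

#' Experimental design of the orientation-adjustment task
#'
#' Eight stimulus offsets from the astigmatic axis, 120-trial blocks
#' (8 offsets x 15 repeats), two blocks per vision state.
#'
#' @param offsets signed design offsets in degrees.
#' @param trials_per_block trials per block; must be a multiple of the
#'   number of offsets.
#' @param blocks_per_state blocks per vision state.
#' @param states vision states present.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(offsets = c(0, 22.5, -22.5, 45, -45,
                                          67.5, -67.5, 90),
                              trials_per_block = 120L,
                              blocks_per_state = 2L,
                              states = c("emmetropic", "astigmatic")) {
  if (trials_per_block %% length(offsets) != 0)
    stop("trials_per_block must be a multiple of the number of offsets")
  structure(list(offsets = offsets,
                 trials_per_block = as.integer(trials_per_block),
                 blocks_per_state = as.integer(blocks_per_state),
                 states = states),
            class = "experiment_design")
}

#' Ground-truth specification of one synthetic eye
#'
#' @param eye_id character id.
#' @param group "chronic" or "control".
#' @param cylinder_power cylindrical power in dioptres (magnitude).
#' @param true_r ground-truth retinal blur; defaults to
#'   [theoretical_r()] at `cylinder_power`.
#' @param gain_loss ground-truth adaptation gain loss a (0 = none).
#' @param base_noise_sd baseline response noise SD in degrees.
#' @param noise_slope extra noise SD per unit |true_r| at the axis
#'   (scaled down linearly toward the orthogonal orientation); applied
#'   under astigmatic viewing only.
#' @param report_bias constant clockwise/counter-clockwise report bias
#'   in degrees.
#' @param axis astigmatic axis in degrees, [0, 180).
#' @param seed integer seed for this eye's trials.
#' @return object of class `synthetic_eye`.
#' @export
synthetic_eye <- function(eye_id, group = c("chronic", "control"),
                          cylinder_power, true_r = NULL, gain_loss = 0,
                          base_noise_sd = 5, noise_slope = 0,
                          report_bias = 0, axis = 0, seed = 1L) {
  group <- match.arg(group)
  if (is.null(true_r)) true_r <- theoretical_r(cylinder = cylinder_power)
  if (base_noise_sd <= 0) stop("base_noise_sd must be positive")
  if (noise_slope < 0) stop("noise_slope must be nonnegative")
  structure(list(eye_id = eye_id, group = group,
                 cylinder_power = cylinder_power, true_r = true_r,
                 gain_loss = gain_loss, base_noise_sd = base_noise_sd,
                 noise_slope = noise_slope, report_bias = report_bias,
                 axis = axis, seed = as.integer(seed)),
            class = "synthetic_eye")
}

#' Generate trial records for one synthetic eye
#'
#' Response model: reported = stimulus + optical error (astigmatic state
#' only, the PSF error curve at `true_r`) + adaptation error (gain loss
#' a, both states) + constant report bias + Gaussian noise.  The noise SD
#' is `base_noise_sd` plus, under astigmatic viewing,
#' `noise_slope * |true_r| * (90 - |offset|) / 90`, so noise grows toward
#' the astigmatic axis where the optical loss of orientation information
#' is largest.  Reports are wrapped to [0, 180).  Fully deterministic
#' given the eye's seed.
#'
#' @param spec a [synthetic_eye()].
#' @param design an [experiment_design()].
#' @param psf optional `psf_table` used to evaluate the optical error
#'   curve (built on demand if NULL).
#' @param sigma_m tuning SD used for the adaptation error curve;
#'   defaults to `base_noise_sd`.
#' @return data frame of trial records with columns eye_id, group,
#'   vision_state, cylinder_power, astigmatic_axis, stimulus_orientation,
#'   reported_orientation.
#' @export
generate_trials <- function(spec, design = experiment_design(), psf = NULL,
                            sigma_m = NULL) {
  if (!inherits(spec, "synthetic_eye")) stop("spec must be a synthetic_eye")
  if (!inherits(design, "experiment_design"))
    stop("design must be an experiment_design")
  if (is.null(psf)) psf <- psf_curve_table()
  if (is.null(sigma_m)) sigma_m <- spec$base_noise_sd
  reps <- design$trials_per_block %/% length(design$offsets)
  off1 <- rep(design$offsets, times = reps * design$blocks_per_state)
  optical <- psf_error_interp(psf, spec$true_r, design$offsets)
  neural <- if (spec$gain_loss != 0) {
    sgn <- ifelse(design$offsets < 0, -1, 1)
    sgn * unname(adaptation_error_curve(spec$gain_loss, sigma_m,
                                        abs(design$offsets)))
  } else rep(0, length(design$offsets))
  prox <- (90 - abs(design$offsets)) / 90      # 1 at the axis, 0 orthogonal
  rows <- with_seed(spec$seed, function() {
    do.call(rbind, lapply(design$states, function(st) {
      astig <- st == "astigmatic"
      mean_err <- (if (astig) optical else 0) + neural + spec$report_bias
      sd_err <- rep(spec$base_noise_sd, length(design$offsets)) +
        (if (astig) spec$noise_slope * abs(spec$true_r) * prox else 0)
      idx <- match(off1, design$offsets)
      err <- mean_err[idx] + stats::rnorm(length(off1), 0, sd_err[idx])
      data.frame(eye_id = spec$eye_id, group = spec$group,
                 vision_state = st,
                 cylinder_power = spec$cylinder_power,
                 astigmatic_axis = spec$axis,
                 stimulus_orientation = wrap_orientation(spec$axis + off1),
                 reported_orientation = wrap_orientation(spec$axis + off1 +
                                                           err))
    }))
  })
  rownames(rows) <- NULL
  rows
}

#' Generate a full synthetic cohort with ground truth
#'
#' Chronic eyes receive cylinder powers sampled on the quarter-dioptre
#' grid in [0.25, 4.00] and a positive adaptation gain loss drawn from a
#' truncated normal centred near 0.3; control eyes are measured at the
#' lens series 0-4 D (each dioptre a separate condition of the same eye)
#' with no adaptation.  Ground-truth blur is the theoretical prediction
#' at each dioptre; compensation in chronic eyes arises purely from the
#' neural gain-loss term.  Control eyes carry the orientation-dependent
#' noise inflation under astigmatic viewing; chronic eyes do not (their
#' compensatory process stabilizes variability).
#'
#' @param n_chronic number of chronic eyes (default 47).
#' @param n_control number of control eyes (default 10).
#' @param master_seed integer master seed; all per-eye seeds derive from
#'   it.
#' @param design an [experiment_design()].
#' @param psf optional `psf_table`.
#' @param base_noise_sd baseline response noise SD (degrees).
#' @param noise_slope control-eye noise inflation per unit |r| at the
#'   axis.
#' @param gain_loss_mean,gain_loss_sd chronic gain-loss distribution
#'   (truncated to [0.02, 0.8]).
#' @param control_lenses dioptre series applied to each control eye.
#' @return list with `trials` (all trial records; control eyes appear
#'   once per lens condition with eye_id "<eye>_D<dioptre>") and `truth`
#'   (one row per eye x condition: eye_id, group, cylinder_power,
#'   true_r, gain_loss, report_bias, seed).
#' @export
generate_cohort <- function(n_chronic = 47L, n_control = 10L,
                            master_seed = 1L, design = experiment_design(),
                            psf = NULL, base_noise_sd = 5,
                            noise_slope = 0.4, gain_loss_mean = 0.29,
                            gain_loss_sd = 0.16,
                            control_lenses = c(0, 1, 2, 3, 4)) {
  if (n_chronic < 1 || n_control < 1) stop("need at least one eye per group")
  if (is.null(psf)) psf <- psf_curve_table()
  draw <- with_seed(master_seed, function() {
    list(cyl = sample(seq(0.25, 4, by = 0.25), n_chronic, replace = TRUE),
         a = pmin(pmax(stats::rnorm(n_chronic, gain_loss_mean,
                                    gain_loss_sd), 0.02), 0.8),
         bias = stats::rnorm(n_chronic + n_control, 0, 1),
         seeds = sample.int(2^20, n_chronic + n_control *
                              length(control_lenses)))
  })
  specs <- list()
  for (i in seq_len(n_chronic)) {
    specs[[length(specs) + 1L]] <-
      synthetic_eye(sprintf("chronic%02d", i), "chronic",
                    cylinder_power = draw$cyl[i], gain_loss = draw$a[i],
                    base_noise_sd = base_noise_sd, noise_slope = 0,
                    report_bias = draw$bias[i], seed = draw$seeds[i])
  }
  si <- n_chronic
  for (i in seq_len(n_control)) {
    for (dpt in control_lenses) {
      si <- si + 1L
      specs[[length(specs) + 1L]] <-
        synthetic_eye(sprintf("control%02d_D%g", i, dpt), "control",
                      cylinder_power = dpt,
                      base_noise_sd = base_noise_sd,
                      noise_slope = noise_slope,
                      report_bias = draw$bias[n_chronic + i],
                      seed = draw$seeds[si])
    }
  }
  trials <- do.call(rbind, lapply(specs, generate_trials,
                                  design = design, psf = psf))
  truth <- do.call(rbind, lapply(specs, function(s)
    data.frame(eye_id = s$eye_id, group = s$group,
               cylinder_power = s$cylinder_power, true_r = s$true_r,
               gain_loss = s$gain_loss, report_bias = s$report_bias,
               seed = s$seed)))
  list(trials = trials, truth = truth)
}
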