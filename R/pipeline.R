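# Tabular I/O for trial records, run configuration with provenance
# hashing, and the end-to-end pipeline: simulate -> profiles -> fits ->
# model comparison -> compensation.

trial_columns <- c("eye_id", "group", "vision_state", "cylinder_power",
                   "astigmatic_axis", "stimulus_orientation",
                   "reported_orientation")

#' Read trial records from CSV
#'
#' Validates the schema and value ranges; malformed rows are reported
#' with their line numbers.
#'
#' @param path CSV file with the columns eye_id, group, vision_state,
#'   cylinder_power, astigmatic_axis, stimulus_orientation,
#'   reported_orientation.
#' @return validated trial data frame.
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_columns, names(tab))
  if (length(missing_cols))
    stop("trial file schema error: missing columns ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) {
    warning("trial file is empty")
    return(tab[, trial_columns])
  }
  bad_orient <- which(tab$stimulus_orientation < 0 |
                        tab$stimulus_orientation >= 180 |
                        tab$reported_orientation < 0 |
                        tab$reported_orientation >= 180 |
                        tab$astigmatic_axis < 0 | tab$astigmatic_axis >= 180)
  if (length(bad_orient))
    stop("orientations outside [0, 180) at file lines: ",
         paste(utils::head(bad_orient + 1L, 10), collapse = ", "))
  bad_grp <- which(!tab$group %in% c("chronic", "control") |
                     !tab$vision_state %in% c("emmetropic", "astigmatic"))
  if (length(bad_grp))
    stop("invalid group/vision_state at file lines: ",
         paste(utils::head(bad_grp + 1L, 10), collapse = ", "))
  tab[, trial_columns]
}

#' Write trial records to CSV
#'
#' @param trials trial data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols))
    stop("trials missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(trials[, trial_columns], path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles raster, optimizer, design, and cohort settings; the
#' configuration hash is embedded in every output for provenance.
#'
#' @param seed master seed for simulation, fitting and bootstrap.
#' @param supersample raster supersample factor.
#' @param n_chronic,n_control cohort sizes.
#' @param n_boot bootstrap replicates for the compensation analysis.
#' @param base_noise_sd,noise_slope synthetic noise model settings.
#' @param sa_control list passed to [sa_minimize()].
#' @param out_dir optional output directory; NULL keeps results in
#'   memory only.
#' @return object of class `run_config` with a `hash` field.
#' @export
run_config <- function(seed = 1L, supersample = 8L, n_chronic = 47L,
                       n_control = 10L, n_boot = 1000L, base_noise_sd = 5,
                       noise_slope = 0.4, sa_control = list(),
                       out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), supersample = as.integer(supersample),
              n_chronic = as.integer(n_chronic),
              n_control = as.integer(n_control),
              n_boot = as.integer(n_boot), base_noise_sd = base_noise_sd,
              noise_slope = noise_slope, sa_control = sa_control,
              out_dir = out_dir)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run config", x$hash, "| seed", x$seed, "| cohort", x$n_chronic,
      "chronic /", x$n_control, "control | f =", x$supersample,
      "| bootstrap", x$n_boot, "\n")
  invisible(x)
}

# profiles for one eye id (or eye x condition) from a trial table
eye_profiles <- function(trials) {
  out <- list()
  if ("astigmatic" %in% trials$vision_state)
    out$astigmatic <- bias_profile(
      trials[trials$vision_state == "astigmatic", , drop = FALSE])
  if ("emmetropic" %in% trials$vision_state)
    out$emmetropic <- bias_profile(
      trials[trials$vision_state == "emmetropic", , drop = FALSE])
  out
}

#' Pooled response-noise SD of one eye
#'
#' Circular SD of the perceptual errors after removing each
#' (state x signed offset) mean, pooled over both vision states.  This
#' estimates the trial-to-trial measurement noise without letting the
#' orientation-dependent bias pattern inflate it, and is the sigma_m
#' handed to the neural observer fits.
#'
#' @param trials trial data frame for one eye.
#' @return scalar SD in degrees.
#' @export
pooled_sigma_m <- function(trials) {
  errs <- unlist(lapply(unique(trials$vision_state), function(st) {
    tr <- trials[trials$vision_state == st, , drop = FALSE]
    e <- debias_errors(signed_error(tr$stimulus_orientation,
                                    tr$reported_orientation))
    off <- wrap_offset(tr$stimulus_orientation - tr$astigmatic_axis)
    grp <- factor(round(off, 6))
    unlist(tapply(e, grp, function(v) v - circ_mean_orient(v)))
  }))
  circ_sd_orient(wrap_offset(errs))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates a cohort (or ingests supplied trials), computes per-eye bias
#' and variability profiles, fits the PSF model per eye x state, fits the
#' adaptation and Bayesian observers per chronic eye, compares models by
#' AICc, and runs the bootstrap compensation analysis of chronic eyes
#' against the control regression.  Deterministic for a fixed
#' configuration; when `config$out_dir` is set, all artifacts are written
#' as CSV/JSON stamped with the configuration hash.
#'
#' @param config a [run_config()].
#' @param trials optional pre-generated trial data frame (with a matching
#'   `truth` attribute optional); NULL simulates a cohort from the
#'   config.
#' @return list with elements `config`, `truth`, `psf_fits` (per eye x
#'   state data frame), `observer_fits` (list of `astig_fit` pairs per
#'   chronic eye), `model_comparison` (AICc summary data frame),
#'   `compensation` (a `compensation_result`), and `variability`
#'   (per-group percent-SD-change table).
#' @export
run_pipeline <- function(config = run_config(), trials = NULL) {
  psf <- psf_curve_table(supersample = config$supersample)
  truth <- NULL
  if (is.null(trials)) {
    cohort <- generate_cohort(config$n_chronic, config$n_control,
                              master_seed = config$seed, psf = psf,
                              base_noise_sd = config$base_noise_sd,
                              noise_slope = config$noise_slope)
    trials <- cohort$trials
    truth <- cohort$truth
  }
  ids <- unique(trials$eye_id)

  psf_rows <- list()
  observer_fits <- list()
  comp_rows <- list()
  for (id in ids) {
    tr <- trials[trials$eye_id == id, , drop = FALSE]
    prof <- eye_profiles(tr)
    grp <- tr$group[1]
    if (!is.null(prof$astigmatic)) {
      fit_a <- astig_fit(prof$astigmatic, model = "psf", psf = psf,
                         seed = config$seed, control = config$sa_control)
      psf_rows[[length(psf_rows) + 1L]] <-
        data.frame(eye_id = id, group = grp,
                   cylinder_power = tr$cylinder_power[1],
                   state = "astigmatic", r = unname(coef(fit_a)["r"]),
                   sse = fit_a$sse, aicc = fit_a$aicc)
    }
    if (!is.null(prof$emmetropic)) {
      fit_e <- astig_fit(prof$emmetropic, model = "psf", psf = psf,
                         seed = config$seed, control = config$sa_control)
      psf_rows[[length(psf_rows) + 1L]] <-
        data.frame(eye_id = id, group = grp,
                   cylinder_power = tr$cylinder_power[1],
                   state = "emmetropic", r = unname(coef(fit_e)["r"]),
                   sse = fit_e$sse, aicc = fit_e$aicc)
    }
    if (grp == "chronic" && length(prof) == 2L) {
      sm <- pooled_sigma_m(tr)
      observer_fits[[id]] <- list(
        adapt = astig_fit(prof, model = "adapt", sigma_m = sm, psf = psf,
                          seed = config$seed, control = config$sa_control),
        bayes = astig_fit(prof, model = "bayes", sigma_m = sm, psf = psf,
                          seed = config$seed, control = config$sa_control))
    }
  }
  psf_fits <- do.call(rbind, psf_rows)

  model_comparison <- NULL
  if (length(observer_fits)) {
    model_comparison <- do.call(rbind, lapply(names(observer_fits),
      function(id) {
        fits <- observer_fits[[id]]
        psf_row <- psf_fits[psf_fits$eye_id == id &
                              psf_fits$state == "astigmatic", ]
        # the PSF model has no neural term: its prediction for the
        # emmetropic state is identically zero, so its emmetropic SSE is
        # the raw sum of squared observed biases (K = 2: r + variance)
        obs_e <- signed_design(eye_profiles(
          trials[trials$eye_id == id, , drop = FALSE])$emmetropic)
        sse_psf_e <- sum(obs_e^2)
        data.frame(eye_id = id,
                   aicc_psf = aicc(psf_row$sse + sse_psf_e, 16L, 2L),
                   aicc_adapt = fits$adapt$aicc,
                   aicc_bayes = fits$bayes$aicc,
                   aicc_emme_psf = aicc(sse_psf_e, 8L, 2L),
                   aicc_emme_adapt = fits$adapt$aicc_emmetropic,
                   aicc_emme_bayes = fits$bayes$aicc_emmetropic,
                   a = unname(coef(fits$adapt)["a"]),
                   sigma_pri = unname(coef(fits$bayes)["sigma_pri"]),
                   r_adapt = unname(coef(fits$adapt)["r"]),
                   r_bayes = unname(coef(fits$bayes)["r"]))
      }))
  }

  astig <- psf_fits[psf_fits$state == "astigmatic", ]
  chronic_tab <- astig[astig$group == "chronic",
                       c("eye_id", "cylinder_power", "r")]
  control_tab <- astig[astig$group == "control",
                       c("eye_id", "cylinder_power", "r")]
  compensation <- NULL
  if (nrow(chronic_tab) && nrow(control_tab)) {
    # control eye x lens conditions share the unit "<eye>"; strip the
    # lens suffix so the bootstrap resamples whole eyes
    control_tab$eye_id <- sub("_D[0-9.]+$", "", control_tab$eye_id)
    compensation <- compensation_analysis(chronic_tab, control_tab,
                                          n_boot = config$n_boot,
                                          seed = config$seed)
  }

  variability <- do.call(rbind, lapply(ids, function(id) {
    tr <- trials[trials$eye_id == id, , drop = FALSE]
    if (length(unique(tr$vision_state)) < 2) return(NULL)
    vp <- variability_profile(tr)
    data.frame(eye_id = id, group = tr$group[1], offset = vp$offsets,
               pct_change = vp$percent_change)
  }))

  result <- list(config = config, truth = truth, psf_fits = psf_fits,
                 observer_fits = observer_fits,
                 model_comparison = model_comparison,
                 compensation = compensation, variability = variability)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  dir.create(result$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) { df$config_hash <- result$config$hash; df }
  outp <- function(name) file.path(result$config$out_dir, name)
  utils::write.csv(stamp(result$psf_fits), outp("psf_fits.csv"),
                   row.names = FALSE)
  if (!is.null(result$model_comparison))
    utils::write.csv(stamp(result$model_comparison),
                     outp("model_comparison.csv"), row.names = FALSE)
  if (!is.null(result$variability))
    utils::write.csv(stamp(result$variability), outp("variability.csv"),
                     row.names = FALSE)
  if (!is.null(result$compensation)) {
    utils::write.csv(stamp(result$compensation$per_eye),
                     outp("compensation_per_eye.csv"), row.names = FALSE)
    comp <- result$compensation
    jsonlite::write_json(
      list(config_hash = result$config$hash, seed = comp$seed,
           intercept = comp$intercept, slope = comp$slope,
           boot_intercept = comp$boot_intercept,
           boot_slope = comp$boot_slope, n_boot = comp$n_boot),
      outp("compensation.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$observer_fits)) {
    fits_json <- lapply(result$observer_fits, function(fits)
      lapply(fits, function(f)
        list(model = f$model, par = as.list(f$par), sse = f$sse, n = f$n,
             k = f$k, aicc = f$aicc, aicc_emmetropic = f$aicc_emmetropic,
             seed = f$seed, config_hash = result$config$hash)))
    jsonlite::write_json(fits_json, outp("observer_fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
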