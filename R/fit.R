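# Model fitting: seeded simulated-annealing global search with local
# polish, small-sample AICc, and the astig_fit S3 class tying the three
# observer models (psf / adapt / bayes) to folded bias profiles.

# run fn with a private, restored RNG stream
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Seeded simulated-annealing minimization with local polish
#'
#' Box-constrained global search: a Gaussian-proposal annealing walk with
#' geometric cooling and restarts, followed by a Nelder-Mead (or
#' golden-section in one dimension) polish of the best point found.
#' Fully deterministic for a given seed.
#'
#' @param fn objective function of a numeric parameter vector.
#' @param lower,upper bounds, same length as the parameter.
#' @param seed integer seed controlling proposals and restarts.
#' @param n_steps annealing steps per restart.
#' @param n_restarts number of annealing restarts (different start
#'   points).
#' @param t0 initial temperature (on the scale of objective
#'   differences).
#' @param cooling geometric cooling factor per step.
#' @return list with `par`, `value`, and `evals`.
#' @export
sa_minimize <- function(fn, lower, upper, seed = 1L, n_steps = 200L,
                        n_restarts = 3L, t0 = 1, cooling = 0.97) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  evals <- 0L
  f_safe <- function(p) {
    evals <<- evals + 1L
    v <- fn(p)
    if (!is.finite(v)) Inf else v
  }
  best <- NULL
  with_seed(seed, function() {
    starts <- lapply(seq_len(n_restarts), function(i)
      lower + stats::runif(d) * (upper - lower))
    starts[[1]] <- (lower + upper) / 2
    for (s in starts) {
      cur <- s; f_cur <- f_safe(cur)
      if (is.null(best) || f_cur < best$value) best <<- list(par = cur, value = f_cur)
      temp <- t0
      scale <- (upper - lower) / 10
      for (k in seq_len(n_steps)) {
        prop <- cur + stats::rnorm(d) * scale
        prop <- pmin(pmax(prop, lower), upper)
        f_prop <- f_safe(prop)
        if (f_prop < f_cur ||
            stats::runif(1) < exp((f_cur - f_prop) / max(temp, 1e-12))) {
          cur <- prop; f_cur <- f_prop
          if (f_cur < best$value) best <<- list(par = cur, value = f_cur)
        }
        temp <- temp * cooling
        scale <- pmax(scale * cooling^(1 / 3), (upper - lower) / 200)
      }
    }
  })
  # local polish from the annealed optimum
  pol <- if (d == 1L) {
    w <- (upper - lower) / 20
    stats::optimize(function(p) f_safe(p),
                    lower = max(lower, best$par - w),
                    upper = min(upper, best$par + w))
  } else {
    f_box <- function(p) f_safe(pmin(pmax(p, lower), upper))
    o <- stats::optim(best$par, f_box, method = "Nelder-Mead",
                      control = list(maxit = 400L, reltol = 1e-10))
    list(minimum = pmin(pmax(o$par, lower), upper), objective = o$value)
  }
  par <- pmin(pmax(if (d == 1L) pol$minimum else pol$minimum, lower), upper)
  val <- if (d == 1L) pol$objective else pol$objective
  if (val < best$value) best <- list(par = par, value = val)
  list(par = best$par, value = best$value, evals = evals)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = N log(SS/N) + 2K + 2K(K+1)/(N - K - 1), the least-squares form
#' with K counting the free parameters plus one (the error variance).
#'
#' @param sse sum of squared errors (> 0; 0 returns -Inf with a
#'   warning, a degenerate perfect fit).
#' @param n number of data points (must exceed K + 1).
#' @param k free parameters plus one.
#' @return AICc value.
#' @export
#' @examples
#' aicc(16, 16, 2)   # 4 + 24/13
aicc <- function(sse, n, k) {
  if (n <= k + 1) stop("aicc: need n > k + 1")
  if (sse < 0) stop("aicc: sse must be nonnegative")
  if (sse == 0) {
    warning("aicc: zero SSE, criterion degenerate (-Inf)")
    return(-Inf)
  }
  n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# observed signed errors at the 8 signed design offsets, mirrored from a
# folded profile (the folded mean at theta is the mean of +theta and
# sign-flipped -theta trials, so the signed curve is +bias at +theta and
# -bias at -theta)
signed_design <- function(profile, offsets = c(-67.5, -45, -22.5, 0,
                                               22.5, 45, 67.5, 90)) {
  j <- match(round(abs(offsets), 6), round(profile$offsets, 6))
  if (any(is.na(j))) stop("profile does not cover the design offsets")
  obs <- profile$mean_bias[j] * ifelse(offsets < 0, -1, 1)
  names(obs) <- offsets
  obs
}

#' Fit an observer model to folded bias profiles
#'
#' The central fitting routine.  For `model = "psf"` a single blur
#' parameter r is fitted to one state's bias profile (8 signed design
#' offsets) by minimizing the sum of squared errors between the observed
#' biases and the PSF error curve, evaluated through the precomputed
#' lookup table.  For `model = "adapt"` or `"bayes"` the pair (r, a) or
#' (r, sigma_pri) is fitted jointly to both vision states (16 points):
#' astigmatic prediction = PSF(r) + neural curve, emmetropic prediction =
#' neural curve alone.  Optimization is a seeded simulated-annealing
#' search with local polish (see [sa_minimize()]).
#'
#' @param profiles for "psf": a single `bias_profile` (or a list with
#'   element `astigmatic`); for the observer models: a list with elements
#'   `emmetropic` and `astigmatic`, both `bias_profile`s.
#' @param model "psf", "adapt", or "bayes".
#' @param sigma_m measurement / likelihood SD in degrees for the neural
#'   models (typically the eye's pooled behavioral SD).  Ignored for
#'   "psf".
#' @param psf a `psf_table` lookup (built on demand if NULL).
#' @param seed optimizer seed.
#' @param bounds named list overriding search bounds: `r` (default
#'   c(-15, 15)), `a` (c(-1, 1)), `sigma_pri` (c(1, 500)).
#' @param control list passed to [sa_minimize()] (n_steps, n_restarts,
#'   t0, cooling).
#' @return object of class `astig_fit`: fitted parameters, SSE, data
#'   points N, K (free parameters + 1), AICc on all N points, AICc on the
#'   emmetropic 8 points alone (observer models), observed and fitted
#'   values, and the seed.
#' @export
#' @examples
#' \donttest{
#' tab <- psf_curve_table(supersample = 4)
#' prof <- list(offsets = c(0, 22.5, 45, 67.5, 90),
#'              mean_bias = psf_error_interp(tab, 3, c(0, 22.5, 45, 67.5, 90)),
#'              n = rep(30, 5))
#' class(prof) <- "bias_profile"
#' astig_fit(prof, model = "psf", psf = tab)
#' }
astig_fit <- function(profiles, model = c("psf", "adapt", "bayes"),
                      sigma_m = NULL, psf = NULL, seed = 1L,
                      bounds = list(), control = list()) {
  model <- match.arg(model)
  if (is.null(psf)) psf <- psf_curve_table()
  b <- utils::modifyList(list(r = c(-15, 15), a = c(-1, 1),
                              sigma_pri = c(1, 500)), bounds)
  ctl <- utils::modifyList(list(n_steps = 200L, n_restarts = 3L, t0 = 5,
                                cooling = 0.97), control)
  sgn_off <- c(-67.5, -45, -22.5, 0, 22.5, 45, 67.5, 90)

  if (model == "psf") {
    prof <- if (inherits(profiles, "bias_profile")) profiles
            else profiles$astigmatic
    if (is.null(prof)) stop("psf fit needs a bias profile")
    if (all(is.na(prof$mean_bias))) stop("empty bias profile")
    obs <- signed_design(prof)
    sse_fn <- function(p) sum((obs - psf_error_interp(psf, p, sgn_off))^2)
    opt <- sa_minimize(sse_fn, b$r[1], b$r[2], seed = seed,
                       n_steps = ctl$n_steps, n_restarts = ctl$n_restarts,
                       t0 = ctl$t0, cooling = ctl$cooling)
    par <- c(r = unname(opt$par))
    fitted_vals <- list(astigmatic = psf_error_interp(psf, par["r"], sgn_off))
    observed <- list(astigmatic = obs)
    n_pts <- length(obs); k <- 2L
    aicc_all <- aicc(opt$value, n_pts, k)
    aicc_emme <- NA_real_
    sse <- opt$value
  } else {
    if (!is.list(profiles) || is.null(profiles$emmetropic) ||
        is.null(profiles$astigmatic))
      stop("observer fit needs both 'emmetropic' and 'astigmatic' profiles")
    if (is.null(sigma_m) || sigma_m <= 0)
      stop("observer fit needs a positive sigma_m")
    obs_a <- signed_design(profiles$astigmatic)
    obs_e <- signed_design(profiles$emmetropic)
    neural_fn <- if (model == "adapt") {
      function(p) ifelse(sgn_off < 0, -1, 1) *
        unname(adaptation_error_curve(p, sigma_m, abs(sgn_off)))
    } else {
      function(p) vapply(sgn_off, function(th)
        wrap_offset(bayes_percept(th, sigma_m, 90, p) - th), numeric(1))
    }
    sse_fn <- function(p) {
      neu <- neural_fn(p[2])
      ret <- psf_error_interp(psf, p[1], sgn_off)
      sum((obs_a - (ret + neu))^2) + sum((obs_e - neu)^2)
    }
    nb <- if (model == "adapt") b$a else b$sigma_pri
    opt <- sa_minimize(sse_fn, c(b$r[1], nb[1]), c(b$r[2], nb[2]),
                       seed = seed, n_steps = ctl$n_steps,
                       n_restarts = ctl$n_restarts, t0 = ctl$t0,
                       cooling = ctl$cooling)
    par <- c(r = unname(opt$par[1]),
             if (model == "adapt") c(a = unname(opt$par[2]))
             else c(sigma_pri = unname(opt$par[2])))
    neu <- neural_fn(opt$par[2])
    ret <- psf_error_interp(psf, opt$par[1], sgn_off)
    fitted_vals <- list(astigmatic = ret + neu, emmetropic = neu)
    observed <- list(astigmatic = obs_a, emmetropic = obs_e)
    n_pts <- length(obs_a) + length(obs_e); k <- 3L
    sse <- opt$value
    aicc_all <- aicc(sse, n_pts, k)
    sse_e <- sum((obs_e - neu)^2)
    aicc_emme <- if (sse_e == 0) -Inf else
      length(obs_e) * log(sse_e / length(obs_e)) + 2 * k +
        2 * k * (k + 1) / (length(obs_e) - k - 1)
  }
  structure(list(model = model, par = par, sse = sse, n = n_pts, k = k,
                 aicc = aicc_all, aicc_emmetropic = aicc_emme,
                 sigma_m = sigma_m, offsets = sgn_off,
                 observed = observed, fitted = fitted_vals,
                 seed = seed, psf = psf),
            class = "astig_fit")
}

#' @export
print.astig_fit <- function(x, digits = 3, ...) {
  cat("Observer model fit (", x$model, ")\n", sep = "")
  cat("Parameters:", paste(names(x$par), "=", round(x$par, digits),
                           collapse = ", "), "\n")
  cat("SSE:", round(x$sse, digits), "on N =", x$n, "points | AICc:",
      round(x$aicc, digits), "\n")
  invisible(x)
}

#' @export
summary.astig_fit <- function(object, ...) {
  res <- unlist(lapply(names(object$observed), function(st)
    object$observed[[st]] - object$fitted[[st]]))
  structure(list(fit = object, residuals = res,
                 rmse = sqrt(object$sse / object$n)),
            class = "summary.astig_fit")
}

#' @export
print.summary.astig_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("RMSE:", round(x$rmse, digits), "deg | AICc (emmetropic 8 pts):",
      round(x$fit$aicc_emmetropic, digits), "\n")
  cat("Residual range: [", round(min(x$residuals), digits), ",",
      round(max(x$residuals), digits), "] deg\n")
  invisible(x)
}

#' @export
coef.astig_fit <- function(object, ...) object$par

#' Predicted perceptual errors from a fitted observer model
#'
#' @param object an `astig_fit`.
#' @param offsets signed stimulus offsets in degrees (must fold onto the
#'   tabulated design offsets).
#' @param state "astigmatic" or "emmetropic".
#' @param ... unused.
#' @return named numeric vector of predicted errors (degrees).
#' @export
predict.astig_fit <- function(object, offsets = object$offsets,
                              state = c("astigmatic", "emmetropic"), ...) {
  state <- match.arg(state)
  r <- object$par[["r"]]
  ret <- psf_error_interp(object$psf, r, offsets)
  neu <- if (object$model == "psf") {
    rep(0, length(offsets))
  } else if (object$model == "adapt") {
    ifelse(offsets < 0, -1, 1) *
      unname(adaptation_error_curve(object$par[["a"]], object$sigma_m,
                                    abs(offsets)))
  } else {
    vapply(offsets, function(th)
      wrap_offset(bayes_percept(th, object$sigma_m, 90,
                                object$par[["sigma_pri"]]) - th),
      numeric(1))
  }
  out <- if (state == "astigmatic") ret + neu else neu
  if (object$model == "psf" && state == "emmetropic")
    out <- rep(0, length(offsets))
  names(out) <- offsets
  out
}

#' @export
fitted.astig_fit <- function(object, ...) object$fitted

#' @export
residuals.astig_fit <- function(object, ...) {
  lapply(names(object$observed), function(st)
    object$observed[[st]] - object$fitted[[st]]) |>
    stats::setNames(names(object$observed))
}

#' @export
plot.astig_fit <- function(x, ...) {
  states <- names(x$observed)
  old <- graphics::par(mfrow = c(1, length(states)))
  on.exit(graphics::par(old))
  for (st in states) {
    graphics::plot(x$offsets, x$observed[[st]], pch = 16,
                   xlab = "offset (deg)", ylab = "error (deg)",
                   main = paste(x$model, "fit,", st), ...)
    graphics::lines(x$offsets, x$fitted[[st]], col = 2)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Simulate trial records from a fitted observer model
#'
#' Generates synthetic orientation-adjustment trials whose generative
#' parameters are the fitted ones: blur r, gain loss a (for the
#' adaptation model), and response noise equal to the fitted sigma_m (or
#' the supplied value).
#'
#' @param object an `astig_fit`.
#' @param nsim number of cohort replicates.
#' @param seed integer seed.
#' @param ... passed to [generate_trials()] (e.g. `design`).
#' @return a trial data frame (one replicate) or a list of them.
#' @export
simulate.astig_fit <- function(object, nsim = 1, seed = 1L, ...) {
  a <- if (object$model == "adapt") object$par[["a"]] else 0
  noise <- if (!is.null(object$sigma_m)) object$sigma_m else 5
  sims <- lapply(seq_len(nsim), function(i) {
    spec <- synthetic_eye(eye_id = paste0("sim", i), group = "chronic",
                          cylinder_power = NA_real_,
                          true_r = object$par[["r"]], gain_loss = a,
                          base_noise_sd = noise, noise_slope = 0,
                          report_bias = 0, seed = seed + i - 1L)
    generate_trials(spec, psf = object$psf, ...)
  })
  if (nsim == 1) sims[[1]] else sims
}
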