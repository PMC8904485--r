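test_that("AICc follows the small-sample least-squares formula", {
  expect_equal(aicc(16, 16, 2), 4 + 12 / 13)
  expect_equal(aicc(8, 16, 3), 16 * log(0.5) + 6 + 24 / 12)
  expect_lt(aicc(8, 16, 2), aicc(16, 16, 2))   # monotone in SSE
  expect_warning(v <- aicc(0, 16, 2), "degenerate")
  expect_identical(v, -Inf)
  expect_error(aicc(1, 4, 3), "n > k")
})

test_that("the annealing optimizer is deterministic and finds easy minima", {
  fn <- function(p) (p[1] - 2)^2 + (p[2] + 1)^2
  o1 <- sa_minimize(fn, c(-5, -5), c(5, 5), seed = 9)
  o2 <- sa_minimize(fn, c(-5, -5), c(5, 5), seed = 9)
  expect_identical(o1$par, o2$par)
  expect_equal(o1$par, c(2, -1), tolerance = 1e-3)
  o3 <- sa_minimize(function(p) sin(3 * p) + 0.1 * p^2, -6, 6, seed = 1)
  expect_equal(o3$par, -0.508, tolerance = 0.01)   # global, not local, well
})

test_that("PSF fit recovers the generating blur from noiseless profiles", {
  tab <- fast_table()
  f3 <- astig_fit(noiseless_profile(3, tab), model = "psf", psf = tab,
                  seed = 2)
  expect_equal(unname(coef(f3)["r"]), 3, tolerance = 0.1)
  f0 <- astig_fit(noiseless_profile(0, tab), model = "psf", psf = tab,
                  seed = 2)
  expect_equal(unname(coef(f0)["r"]), 0, tolerance = 0.1)
  expect_equal(f3$n, 8L)
  expect_equal(f3$k, 2L)
  again <- astig_fit(noiseless_profile(3, tab), model = "psf", psf = tab,
                     seed = 2)
  expect_identical(coef(f3), coef(again))          # same seed, same fit
  expect_error(astig_fit(list(), model = "psf", psf = tab), "profile")
})

test_that("PSF recovery holds across the blur range", {
  tab <- fast_table()
  set.seed(31)
  rs <- runif(20, 0, 10)
  err <- vapply(rs, function(r) {
    fit <- astig_fit(noiseless_profile(r, tab), model = "psf", psf = tab,
                     seed = 5)
    abs(unname(coef(fit)["r"]) - r)
  }, numeric(1))
  expect_lt(max(err), 0.2)
})

test_that("joint observer fit recovers (r, a) from noiseless curves", {
  tab <- fast_table()
  sm <- 8
  pred <- combined_prediction("adapt", 3, 0.3, sm, signed_offsets, psf = tab)
  prof <- profile_pair(
    astig_bias = abs_fold(pred$astigmatic),
    emme_bias = abs_fold(pred$emmetropic))
  fit <- astig_fit(prof, model = "adapt", sigma_m = sm, psf = tab, seed = 4)
  expect_equal(unname(coef(fit)["r"]), 3, tolerance = 0.3)
  expect_equal(unname(coef(fit)["a"]), 0.3, tolerance = 0.03)
  expect_equal(fit$n, 16L)
  expect_equal(fit$k, 3L)
  # data generated by optics alone: the neural term fits to nothing
  prof0 <- profile_pair(psf_error_interp(tab, 3, design_offsets),
                        rep(0, 5))
  fit0 <- astig_fit(prof0, model = "adapt", sigma_m = sm, psf = tab,
                    seed = 4)
  expect_equal(unname(coef(fit0)["a"]), 0, tolerance = 0.02)
  expect_error(astig_fit(prof$astigmatic, model = "adapt", sigma_m = sm,
                         psf = tab), "both")
  expect_error(astig_fit(prof, model = "adapt", psf = tab), "sigma_m")
})

test_that("a Bayesian fit to repulsive adaptation bias flattens its prior", {
  tab <- fast_table()
  sm <- 10
  pred <- combined_prediction("adapt", 3, 0.5, sm, signed_offsets, psf = tab)
  prof <- profile_pair(abs_fold(pred$astigmatic), abs_fold(pred$emmetropic))
  fit <- astig_fit(prof, model = "bayes", sigma_m = sm, psf = tab, seed = 4)
  expect_gt(unname(coef(fit)["sigma_pri"]), 450)   # driven to the bound
})

test_that("compensation is the vertical distance to the control line", {
  control <- data.frame(eye_id = rep(sprintf("c%d", 1:6), each = 5),
                        cylinder_power = rep(0:4, 6),
                        r = rep(2.4 * 0:4, 6))
  chronic <- data.frame(eye_id = c("a", "b"), cylinder_power = c(2, 3),
                        r = c(4.8, 7.2 - 2))
  comp <- compensation_analysis(chronic, control, n_boot = 300, seed = 6)
  expect_equal(comp$per_eye$compensation[1], 0, tolerance = 0.05)
  expect_equal(comp$per_eye$compensation[2], 2, tolerance = 0.05)
  # bootstrap mean line agrees with the point estimate on clean data
  expect_equal(comp$boot_slope, comp$slope, tolerance = 0.01)
  expect_equal(comp$boot_intercept, comp$intercept, tolerance = 0.01)
  expect_error(compensation_analysis(chronic,
                                     control[control$cylinder_power == 2, ]),
               "degenerate")
})

test_that("fitted gain loss tracks compensation when adaptation drives it", {
  # cohort whose only compensatory mechanism is the neural gain loss,
  # with a pronounced enough to be identifiable per eye
  tab <- fast_table()
  a_true <- seq(0.15, 0.85, length.out = 12)
  cyl <- rep(c(1, 2, 3), 4)
  rows <- lapply(seq_along(a_true), function(i) {
    eye <- synthetic_eye(sprintf("e%02d", i), "chronic", cyl[i],
                         gain_loss = a_true[i], base_noise_sd = 10,
                         seed = 300 + i)
    tr <- generate_trials(eye, psf = tab, sigma_m = 10)
    prof <- list(
      astigmatic = bias_profile(tr[tr$vision_state == "astigmatic", ]),
      emmetropic = bias_profile(tr[tr$vision_state == "emmetropic", ]))
    fit_r <- astig_fit(prof$astigmatic, model = "psf", psf = tab, seed = i)
    fit_a <- astig_fit(prof, model = "adapt", sigma_m = pooled_sigma_m(tr),
                       psf = tab, seed = i)
    data.frame(eye_id = eye$eye_id, cylinder_power = cyl[i],
               r = unname(coef(fit_r)["r"]), a = unname(coef(fit_a)["a"]))
  })
  chronic <- do.call(rbind, rows)
  # noise-free control line: the theoretical blur itself
  control <- data.frame(eye_id = rep(c("c1", "c2"), each = 5),
                        cylinder_power = rep(0:4, 2),
                        r = rep(theoretical_r(cylinder = 0:4), 2))
  comp <- compensation_analysis(chronic[, c("eye_id", "cylinder_power", "r")],
                                control, n_boot = 200, seed = 3)
  expect_gt(rank_correlation(chronic$a, comp$per_eye$compensation), 0)
  # stronger adapters are compensated more in truth as well
  expect_gt(rank_correlation(a_true, comp$per_eye$compensation), 0)
})

test_that("Spearman correlation uses midranks and matches hand values", {
  expect_equal(rank_correlation(1:5, 2 * (1:5) + 3), 1)
  expect_equal(rank_correlation(1:5, -(1:5)), -1)
  expect_equal(rank_correlation(1:4, c(2, 1, 4, 3)), 0.6)
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
  expect_error(rank_correlation(1:2, 1:2), "at least 3")
})
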