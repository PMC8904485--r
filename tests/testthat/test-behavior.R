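test_that("signed errors are circular differences in (-90, 90]", {
  expect_equal(signed_error(10, 10), 0)
  expect_equal(signed_error(179, 1), 2)     # wraps across 180
  expect_equal(signed_error(45, 40), -5)
  expect_equal(signed_error(1, 179), -2)
  expect_error(signed_error(200, 10), "0, 180")
})

test_that("debiasing removes the constant report bias and is idempotent", {
  expect_equal(debias_errors(c(2, 2, 2)), c(0, 0, 0))
  expect_equal(debias_errors(c(-4, 0, 4)), c(-4, 0, 4))
  e <- c(-3, 1, 2, 7, -5)
  expect_equal(debias_errors(e + 11), debias_errors(e), tolerance = 1e-9)
  once <- debias_errors(e)
  expect_equal(debias_errors(once), once, tolerance = 1e-9)
  expect_equal(circ_mean_orient(once), 0, tolerance = 1e-9)
  expect_error(debias_errors(numeric(0)), "empty")
})

test_that("folding flips mirror trials and conserves counts", {
  prof <- fold_and_collapse(c(45, -45), c(5, -5))
  expect_equal(prof$mean_bias[prof$offsets == 45], 5)
  prof0 <- fold_and_collapse(signed_offsets, rep(0, 8))
  expect_equal(prof0$mean_bias, rep(0, 5))
  expect_equal(sum(prof0$n), 8L)
  part <- fold_and_collapse(c(0, 90), c(1, -1))
  expect_equal(part$n, c(1L, 0L, 0L, 0L, 1L))
  expect_true(all(is.na(part$mean_bias[2:4])))
  expect_error(fold_and_collapse(30, 1), "outside the design")
})

test_that("folding is invariant under pre-mirroring about the axis", {
  set.seed(42)
  off <- sample(signed_offsets, 200, replace = TRUE)
  err <- rnorm(200, 0, 3)
  a <- fold_and_collapse(off, err)
  b <- fold_and_collapse(-off, -err)      # mirrored dataset
  # oblique offsets are exactly invariant; at 0 and 90 the mirror flips
  # the error sign (these offsets are their own mirror images), so only
  # the magnitude is preserved there
  expect_equal(a$mean_bias[2:4], b$mean_bias[2:4])
  expect_equal(abs(a$mean_bias[c(1, 5)]), abs(b$mean_bias[c(1, 5)]))
  expect_equal(a$n, b$n)
})

test_that("noiseless trials reproduce the generating blur curve exactly", {
  tab <- fast_table()
  r <- 3
  curve <- psf_error_interp(tab, r, signed_offsets)
  stim <- wrap_orientation(signed_offsets)
  rep_ <- wrap_orientation(signed_offsets + curve)
  trials <- data.frame(eye_id = "e", group = "chronic",
                       vision_state = "astigmatic", cylinder_power = 1,
                       astigmatic_axis = 0, stimulus_orientation = stim,
                       reported_orientation = rep_)
  prof <- bias_profile(trials)
  # debiasing subtracts the circular mean of the whole curve; remove the
  # same constant from the reference before comparing
  folded_ref <- fold_and_collapse(signed_offsets,
                                  curve - circ_mean_orient(curve))
  expect_equal(prof$mean_bias, folded_ref$mean_bias, tolerance = 1e-6)
})

test_that("variability profile measures SD change between states", {
  mk <- function(st, off, err) data.frame(
    eye_id = "e", group = "control", vision_state = st, cylinder_power = 1,
    astigmatic_axis = 0, stimulus_orientation = wrap_orientation(off),
    reported_orientation = wrap_orientation(off + err))
  # identical distributions in both states -> zero percent change
  err <- rep(c(-2, 2), each = 8)
  off <- rep(signed_offsets, 2)
  tr <- rbind(mk("emmetropic", off, err), mk("astigmatic", off, err))
  vp <- variability_profile(tr)
  expect_equal(vp$percent_change, rep(0, 5), tolerance = 1e-9)
  # doubling the spread at one offset -> +100 percent there
  off2 <- rep(45, 20)
  tr2 <- rbind(mk("emmetropic", off2, rep(c(-1, 1), 10)),
               mk("astigmatic", off2, rep(c(-2, 2), 10)))
  vp2 <- variability_profile(tr2)
  expect_equal(vp2$percent_change[3], 100, tolerance = 1)
  expect_error(variability_profile(mk("astigmatic", off, err)),
               "both vision states")
})

test_that("folded variability is not inflated by the bias pattern", {
  # +-45 trials with equal and opposite mean biases but equal spread:
  # after folding, the SD must reflect only the spread
  off <- rep(c(45, -45), each = 10)
  err <- c(10 + rep(c(-1, 1), 5), -10 + rep(c(-1, 1), 5))
  tr <- data.frame(eye_id = "e", group = "control",
                   vision_state = rep(c("emmetropic", "astigmatic"),
                                      each = 20),
                   cylinder_power = 1, astigmatic_axis = 0,
                   stimulus_orientation = wrap_orientation(rep(off, 2)),
                   reported_orientation = wrap_orientation(rep(off, 2) +
                                                             rep(err, 2)))
  vp <- variability_profile(tr)
  expect_lt(vp$sd_per_offset[3, 1], 1.5)   # ~1, not ~10
})
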