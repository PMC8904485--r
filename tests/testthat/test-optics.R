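test_that("theoretical blur is zero at emmetropia and increasing in cylinder", {
  expect_identical(theoretical_r(cylinder = 0), 0)
  # hand evaluation of the focal-length chain (all lengths in mm,
  # alpha = cylinder/1000): P = 0.02, N_emme = 23.7624, N_astig(1D) =
  # 23.2109 -> B = 0.0680 -> B/P - 1 = 2.40
  expect_equal(theoretical_r(cylinder = 1), 2.40, tolerance = 1e-3)
  expect_equal(theoretical_r(cylinder = 4), 9.60, tolerance = 1e-3)
  alphas <- seq(0, 4, by = 0.25)
  rs <- theoretical_r(cylinder = alphas)
  expect_true(all(diff(rs) > 0))
  expect_gt(theoretical_r(cylinder = 4), theoretical_r(cylinder = 1))
  expect_error(optical_config(pupil_diameter = -1), "positive")
  expect_error(theoretical_r(cylinder = -50000), "domain")
})

test_that("blur kernel has unit mass, elliptical support, and axis swap", {
  for (r in c(-15, -5, -0.3, 0, 0.3, 5, 15)) for (f in c(1L, 4L, 8L)) {
    k <- build_kernel(r, f)
    expect_equal(sum(k$weights), 1, tolerance = 1e-9)
    expect_true(all(k$weights >= 0))
    # symmetric under reflection about both principal axes
    expect_equal(k$weights, k$weights[rev(seq_len(nrow(k$weights))), ])
    expect_equal(k$weights, k$weights[, rev(seq_len(ncol(k$weights)))])
  }
  k0 <- build_kernel(0, 1L)
  expect_equal(nrow(k0$weights), ncol(k0$weights))  # circular at r = 0
  k5 <- build_kernel(5, 4L)
  # semi-axis ratio 6:1 between elongation (orthogonal, columns) and axis
  expect_equal(ncol(k5$weights) - 1L, 6L * (nrow(k5$weights) - 1L))
  km <- build_kernel(-5, 4L)
  expect_equal(km$weights, t(k5$weights))            # transpose under r -> -r
})

test_that("rendered Gabor has the stated symmetry, contrast, and cycles", {
  sp <- gabor_spec()
  img <- render_gabor(0, sp, supersample = 4L)
  # offset 0, sine phase: odd symmetry about the axis direction
  lum <- img$luminance
  expect_equal(lum, 2 * sp$background_luminance -
                 lum[, rev(seq_len(ncol(lum)))], tolerance = 1e-12)
  expect_true(all(lum >= 0 & lum <= 1))
  # contrast 0 degenerates to the uniform background
  flat <- render_gabor(45, gabor_spec(michelson_contrast = 0),
                       supersample = 4L)
  expect_true(all(flat$luminance == sp$background_luminance))
  # 2 cyc/deg across a 0.5-deg envelope: a full carrier period fits
  expect_gte(sp$spatial_frequency * 2 * sp$envelope_radius, 1)
  expect_error(render_gabor(0, gabor_spec(), supersample = 4L,
                            window = 0.1), "envelope")
})

test_that("blurring preserves mean luminance and fixes uniform images", {
  img <- render_gabor(45, supersample = 4L)
  k <- build_kernel(3, 4L)
  out <- blur_image(img, k)
  expect_equal(mean(out$luminance), mean(img$luminance), tolerance = 1e-6)
  flat <- render_gabor(45, gabor_spec(michelson_contrast = 0),
                       supersample = 4L)
  outf <- blur_image(flat, k)
  expect_equal(outf$luminance, flat$luminance, tolerance = 1e-12)
  expect_error(blur_image(img, build_kernel(3, 8L)), "supersample")
})

test_that("identity kernel leaves the image unchanged", {
  img <- render_gabor(22.5, supersample = 4L)
  k1 <- build_kernel(0, 1L)
  k1$supersample <- 4L          # single-cell limit acting on the f=4 raster
  k1$weights <- matrix(1, 1, 1)
  expect_equal(blur_image(img, k1)$luminance, img$luminance)
})

test_that("decoder recovers the stimulus orientation of unblurred Gabors", {
  for (th in signed_offsets) {
    img <- render_gabor(th, supersample = 4L)
    expect_lt(abs(wrap_offset(decode_orientation(img) - th)), 0.01)
  }
  flat <- render_gabor(0, gabor_spec(michelson_contrast = 0),
                       supersample = 4L)
  expect_error(decode_orientation(flat), "decode failure")
})

test_that("blur error curve is antisymmetric with zero bias on the axes", {
  for (r in c(2, 6)) {
    err <- psf_error_curve(r, c(0, 90, 22.5, -22.5, 67.5, -67.5),
                           supersample = 4L)
    expect_lt(abs(err[["0"]]), 1)
    expect_lt(abs(err[["90"]]), 1)
    expect_equal(err[["22.5"]], -err[["-22.5"]], tolerance = 0.5)
    expect_equal(err[["67.5"]], -err[["-67.5"]], tolerance = 0.5)
  }
})

test_that("oblique blur bias points away from the axis and grows with r", {
  errs <- vapply(c(0, 1, 2, 3, 5), function(r)
    psf_error_curve(r, 45, supersample = 4L)[[1]], numeric(1))
  expect_true(all(diff(abs(errs)) > 0))
  expect_true(all(errs[-1] > 0))      # repelled from the axis for r > 0
  # r < 0 mirrors the curve: bias of -r at theta equals the negated bias
  # of +r at 90 - theta
  e_neg <- psf_error_curve(-5, 45, supersample = 4L)[[1]]
  expect_equal(e_neg, -errs[5], tolerance = 0.5)
})

test_that("decoded bias agrees across supersampling factors", {
  for (r in c(1, 5, 10)) {
    e4 <- psf_error_curve(r, 45, supersample = 4L)[[1]]
    e8 <- psf_error_curve(r, 45, supersample = 8L)[[1]]
    expect_lt(abs(e4 - e8), 1)
  }
})

test_that("lookup table interpolates the direct chain closely", {
  tab <- fast_table()
  for (r in c(-7.23, 0, 1.55, 4.9)) {
    direct <- psf_error_curve(r, design_offsets, supersample = 4L)
    interp <- psf_error_interp(tab, r, design_offsets)
    expect_lt(max(abs(direct - interp)), 0.2)
  }
  # signed offsets fold antisymmetrically
  expect_equal(psf_error_interp(tab, 3, -45), -psf_error_interp(tab, 3, 45))
  expect_error(psf_error_interp(tab, 3, 30), "not tabulated")
})
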