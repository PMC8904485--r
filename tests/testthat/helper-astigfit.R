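# Shared fixtures.  Unit tests run the image chain at supersample 4 for
# speed; the package-session cache makes repeated table requests free.

fast_table <- function() psf_curve_table(supersample = 4L)

design_offsets <- c(0, 22.5, 45, 67.5, 90)
signed_offsets <- c(-67.5, -45, -22.5, 0, 22.5, 45, 67.5, 90)

# noiseless folded bias profile generated from the blur curve at r
noiseless_profile <- function(r, tab = fast_table()) {
  structure(list(offsets = design_offsets,
                 mean_bias = psf_error_interp(tab, r, design_offsets),
                 n = rep(60L, 5L)),
            class = "bias_profile")
}

# fold a curve evaluated at signed_offsets onto the five design offsets
# (curves are antisymmetric, so the folded value is the +theta value)
abs_fold <- function(curve) curve[match(design_offsets, signed_offsets)]

# profile pair (both states) from explicit astigmatic/emmetropic curves
profile_pair <- function(astig_bias, emme_bias) {
  mk <- function(b) structure(list(offsets = design_offsets, mean_bias = b,
                                   n = rep(60L, 5L)), class = "bias_profile")
  list(astigmatic = mk(astig_bias), emmetropic = mk(emme_bias))
}
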