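# The chronic group's refractive-error table (auto-refractometer
# measurements of the naked eye and the daily eyeglass under-correction),
# transcribed from the published study table.  Eyes whose data the study
# discarded (high cylinder or high daily under-correction) appear as NA
# rows, as in the printed table.

#' Refractive errors of the chronic astigmatism group
#'
#' One row per participant x eye (27 participants, both eyes) with the
#' naked-eye spherical and cylindrical refractive errors (dioptre), the
#' cylindrical axis (degrees), and the residual refractive errors of the
#' daily eyeglasses (under-correction).  Discarded eyes are NA rows.
#'
#' @return data frame with columns participant, sex, age, eye,
#'   naked_spherical, naked_cylinder, naked_axis, daily_spherical,
#'   daily_cylinder.
#' @export
#' @examples
#' tab <- chronic_refraction()
#' nrow(apply_refraction_exclusions(tab))   # 47 retained eyes
chronic_refraction <- function() {
  path <- system.file("extdata", "chronic_refraction.csv",
                      package = "astigfit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Apply the study's eye-exclusion rules
#'
#' Retains eyes with complete measurements whose naked cylindrical power
#' does not exceed `max_cylinder` in magnitude and whose daily
#' under-corrected cylindrical error is not below `min_daily_cylinder`
#' (i.e. no more negative than -1.00 D).
#'
#' @param tab data frame from [chronic_refraction()].
#' @param max_cylinder largest retained cylinder magnitude (dioptre).
#' @param min_daily_cylinder most negative retained daily cylindrical
#'   under-correction (dioptre).
#' @return the retained rows.
#' @export
apply_refraction_exclusions <- function(tab, max_cylinder = 4,
                                        min_daily_cylinder = -1) {
  keep <- !is.na(tab$naked_cylinder) &
    abs(tab$naked_cylinder) <= max_cylinder &
    tab$daily_cylinder >= min_daily_cylinder
  tab[keep, , drop = FALSE]
}
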