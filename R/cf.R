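# Hidden-fraction correction factor.
#
# Small liposomes diffract too weakly to be detected in scatter mode but
# remain visible by fluorescence. Measuring the same fully fluorescent
# sample in both channels quantifies the deficit bin by bin:
#   CF = (Fluo - Diff) / Diff
# and the corrected diffraction curve is Diff * (1 + CF). The correction
# is meant for strongly affected preparations (50-nm-extruded liposomes)
# and is applied explicitly, never automatically.

#' Compute the correction-factor curve from a calibration sample
#'
#' @param fluo Fluorescence-channel `size_distribution` of a fully
#'   fluorescent calibration sample.
#' @param diff Diffraction-channel `size_distribution` of the same sample,
#'   on the same bin grid.
#' @return A tibble of class `cf_curve`: `bin_centre`, `cf`, `valid`.
#'   Bins where the diffraction concentration is zero carry no information
#'   about the deficit and are flagged invalid (`cf = NA`).
#' @export
#' @seealso [apply_cf()], [align_distributions()]
compute_cf <- function(fluo, diff) {
  check_distribution(fluo, "fluo")
  check_distribution(diff, "diff")
  check_same_binning(fluo, diff)
  valid <- diff$concentration > 0
  cf <- ifelse(valid, (fluo$concentration - diff$concentration) / diff$concentration,
    NA_real_
  )
  out <- tibble(bin_centre = diff$bin_centre, cf = cf, valid = valid)
  structure(out,
    bin_width = attr(diff, "bin_width"),
    class = c("cf_curve", class(out))
  )
}

#' Apply a correction-factor curve to a diffraction distribution
#'
#' Rescales each valid bin by `1 + CF`; invalid bins pass through
#' unchanged (their count is reported in a message). By construction,
#' `apply_cf(diff, compute_cf(fluo, diff))` reproduces `fluo` exactly on
#' all valid bins.
#'
#' @param diff Diffraction-channel `size_distribution`.
#' @param cf A `cf_curve` from [compute_cf()] on the same bin grid.
#' @return The corrected `size_distribution`.
#' @export
apply_cf <- function(diff, cf) {
  check_distribution(diff, "diff")
  if (!inherits(cf, "cf_curve")) {
    abort("`cf` must come from compute_cf().")
  }
  if (nrow(cf) != nrow(diff) ||
    !isTRUE(all.equal(cf$bin_centre, diff$bin_centre)) ||
    !isTRUE(all.equal(attr(cf, "bin_width"), attr(diff, "bin_width")))) {
    abort("`cf` is on a different bin grid than `diff`.")
  }
  n_invalid <- sum(!cf$valid)
  if (n_invalid > 0L) {
    inform(sprintf("%d bin(s) without a valid CF passed through uncorrected.", n_invalid))
  }
  corrected <- ifelse(cf$valid, diff$concentration * (1 + cf$cf), diff$concentration)
  rebuild_distribution(
    tibble(bin_centre = diff$bin_centre, concentration = corrected), diff
  )
}

#' Regrid a correction-factor curve onto a distribution's bin grid
#'
#' The CF is estimated once from a fluorescent calibration sample and then
#' applied to separately measured diffraction distributions, whose bin
#' range rarely coincides with the calibration's. This puts the curve onto
#' the target grid; bins the calibration did not cover become invalid
#' (and so pass through [apply_cf()] uncorrected).
#'
#' @param cf A `cf_curve`.
#' @param template A `size_distribution` whose grid to adopt.
#' @return A `cf_curve` on `template`'s grid.
#' @export
regrid_cf <- function(cf, template) {
  if (!inherits(cf, "cf_curve")) abort("`cf` must come from compute_cf().")
  check_distribution(template, "template")
  w <- attr(template, "bin_width")
  if (!isTRUE(all.equal(w, attr(cf, "bin_width")))) {
    abort("bin widths differ.")
  }
  idx <- match(round(template$bin_centre / w * 2), round(cf$bin_centre / w * 2))
  cf_vals <- ifelse(is.na(idx), NA_real_, cf$cf[replace(idx, is.na(idx), 1L)])
  valid_vals <- !is.na(idx) & cf$valid[replace(idx, is.na(idx), 1L)]
  out <- tibble(
    bin_centre = template$bin_centre,
    cf = cf_vals,
    valid = valid_vals
  )
  structure(out, bin_width = w, class = c("cf_curve", class(out)))
}
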