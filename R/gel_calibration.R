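# Apparent-mass calibration: log10(mass) is modelled as a linear function of
# slice index, the standard calibration for gradient native gels.  With two
# markers the fit interpolates them exactly; with more, it is least squares
# and the RMS residual diagnoses model adequacy.

#' Fit a slice-to-mass calibration from markers
#'
#' @param markers Data frame with columns `marker_name`, `mass_kda`,
#'   `peak_slice` (>= 2 markers at distinct slices, mass strictly decreasing
#'   with slice).
#' @param n_slices Number of gel slices the calibration is defined over
#'   (used only to warn about extrapolation; default: the marker range).
#' @return Object of class `mass_calibration` with `slope`, `intercept`
#'   (log10 kDa per slice / at slice 0), `n_markers`, `rms_log10` and
#'   `slice_range`.
#' @export
#' @examples
#' mk <- data.frame(marker_name = c("a", "b"), mass_kda = c(1000, 100),
#'                  peak_slice = c(10, 30))
#' cal <- fit_mass_calibration(mk)
#' apparent_mass(cal, 20)  # 316.23 kDa
fit_mass_calibration <- function(markers, n_slices = NULL) {
  markers <- validate_markers(markers)
  fit <- stats::lm(log10(mass_kda) ~ peak_slice, data = markers)
  coefs <- stats::coef(fit)
  slope <- unname(coefs[["peak_slice"]])
  if (slope >= 0) stopf("calibration slope must be negative (mass decreases down the gel)")
  rms <- sqrt(mean(stats::residuals(fit)^2))
  structure(
    list(slope = slope, intercept = unname(coefs[["(Intercept)"]]),
         n_markers = nrow(markers), rms_log10 = rms,
         slice_range = c(1, n_slices %||% max(markers$peak_slice))),
    class = "mass_calibration")
}

#' @export
print.mass_calibration <- function(x, ...) {
  cat(sprintf(
    "<mass_calibration> log10(kDa) = %.5f %+.5f * slice  (%d markers, RMS %.2e)\n",
    x$intercept, x$slope, x$n_markers, x$rms_log10))
  invisible(x)
}

#' Apparent molecular mass at a slice position
#'
#' @param calibration A `mass_calibration`.
#' @param slice Continuous slice coordinate(s).  Values outside the
#'   calibrated range are extrapolated with a warning.
#' @return Apparent mass in kDa.
#' @export
apparent_mass <- function(calibration, slice) {
  rng <- calibration$slice_range
  if (any(slice < rng[1L] | slice > rng[2L]))
    warnf("slice outside the calibrated range [%g, %g]; extrapolating",
          rng[1L], rng[2L])
  10^(calibration$intercept + calibration$slope * slice)
}

#' Slice position of an apparent mass (inverse calibration)
#'
#' @param calibration A `mass_calibration`.
#' @param mass_kda Apparent mass in kDa.
#' @return Continuous slice coordinate.
#' @export
mass_to_slice <- function(calibration, mass_kda) {
  (log10(mass_kda) - calibration$intercept) / calibration$slope
}

#' Self-calibration from the reference condition's marker complexes
#'
#' Builds a marker table without external standards: the two gel endpoints
#' (from the gel model's mass range) plus the detected migration peaks of
#' complexes of known mass in the reference condition -- by default the free
#' complex III dimer (500 kDa, via UQCRC2) and the complex V monomer
#' (700 kDa, via ATP5MC1).  For each marker complex, the profile peak
#' nearest the endpoint-implied position is used; markers whose peak cannot
#' be located are dropped with a warning.
#'
#' @param profile_set Normalised profiles from [build_profiles()].
#' @param gel A [gel_model()].
#' @param condition Reference condition the marker complexes are intact in.
#' @param marker_defs Data frame `marker_name`, `protein_id`, `mass_kda`.
#' @param max_offset Maximum distance (slices) between expected and detected
#'   peak for a marker to be accepted.
#' @return A `mass_calibration`; the marker table used is attached as
#'   attribute `markers`.
#' @export
self_calibration <- function(profile_set, gel, condition,
                             marker_defs = default_marker_defs(),
                             max_offset = 3) {
  endpoints <- data.frame(
    marker_name = c("gel_top", "gel_bottom"),
    mass_kda = 10^c(gel$log10_mass_top, gel$log10_mass_bottom),
    peak_slice = c(1, gel$n_slices), stringsAsFactors = FALSE)
  prior <- fit_mass_calibration(endpoints, n_slices = gel$n_slices)
  found <- list()
  for (i in seq_len(nrow(marker_defs))) {
    def <- marker_defs[i, ]
    prof <- tryCatch(profile_get(profile_set, def$protein_id, condition),
                     error = function(e) NULL)
    if (is.null(prof)) {
      warnf("marker '%s': no profile for %s; skipped", def$marker_name,
            def$protein_id)
      next
    }
    peaks <- detect_peaks(prof, min_rel_height = 0.1)
    if (nrow(peaks) == 0L) next
    expected <- mass_to_slice(prior, def$mass_kda)
    j <- which.min(abs(peaks$slice - expected))
    if (abs(peaks$slice[j] - expected) > max_offset) {
      warnf("marker '%s': nearest peak %.1f slices from expected; skipped",
            def$marker_name, abs(peaks$slice[j] - expected))
      next
    }
    found[[length(found) + 1L]] <- data.frame(
      marker_name = def$marker_name, mass_kda = def$mass_kda,
      peak_slice = peaks$slice[j], stringsAsFactors = FALSE)
  }
  markers <- rbind(endpoints, do.call(rbind, found))
  cal <- fit_mass_calibration(markers, n_slices = gel$n_slices)
  attr(cal, "markers") <- validate_markers(markers)
  cal
}

#' Default marker complexes for self-calibration
#'
#' @return Data frame `marker_name`, `protein_id`, `mass_kda`.
#' @export
default_marker_defs <- function() {
  data.frame(
    marker_name = c("III2_dimer", "cV_monomer"),
    protein_id = c("UQCRC2", "ATP5MC1"),
    mass_kda = c(500, 700), stringsAsFactors = FALSE)
}
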