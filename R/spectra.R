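#' Absorbance spectrum
#'
#' Container for a UV-vis absorbance spectrum, typically recorded over
#' 350-500 nm where the Soret band of heme/hemoglobin (peak near 410 nm)
#' dominates. Wavelengths must be strictly increasing and absorbances finite.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing.
#' @param absorbances Numeric vector of absorbances (unitless), same length.
#' @param label Free-text label for the measurement.
#'
#' @return An object of class `ilx_spectrum`: a list with elements
#'   `wavelengths`, `absorbances`, `label`.
#' @examples
#' s <- spectrum_data(c(350, 410, 500), c(0.2, 1.0, 0.1), label = "serum")
#' absorbance_at(s, 410)
#' @export
spectrum_data <- function(wavelengths, absorbances, label = "") {
  .check_number(wavelengths, "wavelengths")
  .check_number(absorbances, "absorbances")
  if (length(wavelengths) != length(absorbances)) {
    .stop_validation("wavelengths and absorbances must have equal length")
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    .stop_validation("wavelengths must be strictly increasing")
  }
  structure(
    list(wavelengths = as.numeric(wavelengths),
         absorbances = as.numeric(absorbances),
         label = as.character(label)[1]),
    class = "ilx_spectrum"
  )
}

#' @export
print.ilx_spectrum <- function(x, ...) {
  cat(sprintf("Absorbance spectrum '%s': %d points, %.6g-%.6g nm\n",
              x$label, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Read and write spectra as CSV
#'
#' Spectra are exchanged as two-column CSV files with header
#' `wavelength_nm,absorbance`. Malformed rows are reported by line number;
#' non-monotone wavelengths fail validation.
#'
#' @param path Path to a CSV file.
#' @param label Label attached to the spectrum read (defaults to the file name).
#' @return `read_spectrum` returns an [spectrum_data()] object;
#'   `write_spectrum` returns `path` invisibly.
#' @export
read_spectrum <- function(path, label = basename(path)) {
  df <- .read_numeric_csv(path, c("wavelength_nm", "absorbance"))
  spectrum_data(df$wavelength_nm, df$absorbance, label = label)
}

#' @rdname read_spectrum
#' @param spec A spectrum object.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "ilx_spectrum"))
  .write_csv_full(data.frame(wavelength_nm = spec$wavelengths,
                             absorbance = spec$absorbances), path)
}

#' Absorbance at a wavelength
#'
#' Returns the absorbance at `wavelength`, exact at grid points and linearly
#' interpolated between bracketing points. Queries outside the recorded range
#' are an error rather than an extrapolation.
#'
#' @param spec A [spectrum_data()] object.
#' @param wavelength Query wavelength in nm, within the recorded range.
#' @return Absorbance (unitless scalar).
#' @export
absorbance_at <- function(spec, wavelength) {
  stopifnot(inherits(spec, "ilx_spectrum"))
  .check_number(wavelength, "wavelength")
  if (length(wavelength) != 1) .stop_validation("wavelength must be scalar")
  rng <- range(spec$wavelengths)
  if (wavelength < rng[1] || wavelength > rng[2]) {
    .stop_validation(sprintf(
      "wavelength %g nm outside recorded range [%g, %g] nm",
      wavelength, rng[1], rng[2]))
  }
  if (length(spec$wavelengths) == 1) return(spec$absorbances)
  approx(spec$wavelengths, spec$absorbances, xout = wavelength)$y
}

#' Beer-Lambert calibration for Soret-band quantification
#'
#' Proportionality between absorbance at the analytical wavelength and
#' hemoglobin concentration, `A = slope * c`. The default slope corresponds
#' to an absorbance of 1 at 0.15 mg/mL hemoglobin measured at 410 nm, the
#' working calibration of the spectrophotometric assay; it folds the molar
#' absorptivity and path length into a single constant and can be overridden
#' when the instrument is calibrated differently.
#'
#' @param slope Absorbance per (mg/mL) at `wavelength`; must be positive.
#' @param wavelength Analytical wavelength in nm (default 410, the Soret peak).
#' @return An object of class `ilx_beer_lambert`.
#' @export
beer_lambert_calibration <- function(slope = 1 / 0.15, wavelength = 410) {
  .check_number(slope, "slope", lower = 0, strict_lower = TRUE)
  .check_number(wavelength, "wavelength", lower = 0, strict_lower = TRUE)
  structure(list(slope = slope, wavelength = wavelength),
            class = "ilx_beer_lambert")
}

#' Concentration from absorbance
#'
#' Inverts the Beer-Lambert proportionality: `c = A / slope`. Linear and
#' homogeneous in `A`; negative absorbances are rejected.
#'
#' @param a Absorbance (unitless, >= 0). Vectorized.
#' @param cal A [beer_lambert_calibration()] object.
#' @return Concentration in mg/mL.
#' @export
concentration_from_absorbance <- function(a, cal = beer_lambert_calibration()) {
  stopifnot(inherits(cal, "ilx_beer_lambert"))
  .check_number(a, "absorbance", lower = 0)
  a / cal$slope
}

#' Extraction efficiency from before/after absorbances
#'
#' Percentage of the absorbing species removed by the extraction, computed on
#' absorbances at the analytical wavelength:
#' `100 * (A_before - A_after) / A_before`. Under Beer-Lambert linearity this
#' equals the efficiency computed on concentrations. An after-measurement
#' exceeding the before-measurement would imply negative efficiency and
#' signals a measurement problem, so it raises rather than clips.
#'
#' @param a_before Absorbance before extraction (> 0).
#' @param a_after Absorbance after extraction (>= 0, <= `a_before`).
#' @return Efficiency in percent, in `[0, 100]`.
#' @examples
#' extraction_efficiency(1.0, 0.0511) # 94.89
#' @export
extraction_efficiency <- function(a_before, a_after) {
  .check_number(a_before, "a_before", lower = 0, strict_lower = TRUE)
  .check_number(a_after, "a_after", lower = 0)
  if (any(a_after > a_before)) {
    .stop_validation("a_after exceeds a_before: negative efficiency ",
                     "signals a measurement problem")
  }
  100 * (a_before - a_after) / a_before
}
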