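#' Standard wavelength grids
#'
#' The imaging method works on two fixed wavelength grids: spectral
#' reconstruction from RGB is performed on a 29-channel grid from 420 to
#' 700 nm at 10 nm intervals, and chromophore analysis (absorbance
#' regression) uses the 16-channel subset from 500 to 650 nm at 10 nm
#' intervals, where the visible hemoglobin bands live.
#'
#' @param which `"reconstruction"` (29 channels, 420-700 nm) or
#'   `"analysis"` (16 channels, 500-650 nm).
#' @return Numeric vector of wavelengths in nm, strictly increasing with a
#'   uniform 10 nm step.
#' @examples
#' length(wavelength_grid("reconstruction"))  # 29
#' length(wavelength_grid("analysis"))        # 16
#' @export
wavelength_grid <- function(which = c("reconstruction", "analysis")) {
  which <- match.arg(which)
  if (which == "reconstruction") seq(420, 700, by = 10) else seq(500, 650, by = 10)
}

#' Indices of the analysis grid within the reconstruction grid
#'
#' @return Integer vector of length 16 such that
#'   `wavelength_grid("reconstruction")[analysis_indices()]` equals
#'   `wavelength_grid("analysis")`.
#' @export
analysis_indices <- function() {
  match(wavelength_grid("analysis"), wavelength_grid("reconstruction"))
}

# internal: check a wavelength vector is a uniform increasing grid
assert_uniform_grid <- function(wl) {
  if (length(wl) < 2L || any(diff(wl) <= 0) ||
      max(abs(diff(wl) - diff(wl)[1])) > 1e-9) {
    stop("wavelengths must be strictly increasing with a uniform step")
  }
  invisible(wl)
}
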