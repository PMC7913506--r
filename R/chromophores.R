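#' Chromophore extinction spectra and absorption-coefficient builders
#'
#' The skin model contains four absorbers: methemoglobin (metHb),
#' oxygenated hemoglobin (HbO), deoxygenated hemoglobin (HbR) and melanin.
#' Extinction-coefficient tabulations for the three hemoglobin derivatives
#' (molar extinction, L mol^-1 cm^-1) and an absorption spectrum for
#' melanosomes (mm^-1 at unit volume fraction) are bundled as CSV assets
#' covering 400-700 nm; see `inst/extdata/chromophores/`.
#'
#' @name chromophores
NULL

.chromophore_names <- c("metHb", "HbO", "HbR", "melanin")

.chromophore_file <- function(name) {
  file <- switch(name,
    metHb   = "methb.csv",
    HbO     = "hbo.csv",
    HbR     = "hbr.csv",
    melanin = "melanin.csv")
  system.file("extdata", "chromophores", file, package = "hemospect",
              mustWork = TRUE)
}

# cache of native tabulations, filled lazily
.chromophore_cache <- new.env(parent = emptyenv())

#' Load a bundled extinction-coefficient spectrum
#'
#' Reads the bundled tabulation for one chromophore and, if `wavelengths`
#' is given, resamples it by linear interpolation. Queries outside the
#' tabulated range are an error (no extrapolation).
#'
#' @param name One of `"metHb"`, `"HbO"`, `"HbR"`, `"melanin"`.
#' @param wavelengths Optional numeric vector of wavelengths (nm) on which
#'   to resample. Defaults to the native 400-700 nm tabulation grid.
#' @return An object of class `chromophore_spectrum`: a list with elements
#'   `name`, `wavelengths` (nm) and `epsilon` (L mol^-1 cm^-1 for the
#'   hemoglobins; mm^-1 per unit melanosome volume fraction for melanin).
#' @examples
#' hbo <- load_extinction("HbO", wavelength_grid("analysis"))
#' plot(hbo$wavelengths, hbo$epsilon, type = "b")
#' @export
load_extinction <- function(name, wavelengths = NULL) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% .chromophore_names)) {
    stop("unknown chromophore '", paste(name, collapse = ","),
         "'; valid names are: ", paste(.chromophore_names, collapse = ", "))
  }
  if (is.null(.chromophore_cache[[name]])) {
    tab <- read.csv(.chromophore_file(name), comment.char = "#")
    stopifnot(identical(names(tab), c("wavelength_nm", "epsilon")),
              all(tab$epsilon >= 0))
    .chromophore_cache[[name]] <- tab
  }
  tab <- .chromophore_cache[[name]]
  if (is.null(wavelengths)) {
    wl <- tab$wavelength_nm
    eps <- tab$epsilon
  } else {
    if (any(wavelengths < min(tab$wavelength_nm) - 1e-9) ||
        any(wavelengths > max(tab$wavelength_nm) + 1e-9)) {
      stop("requested wavelengths outside the tabulated range ",
           min(tab$wavelength_nm), "-", max(tab$wavelength_nm),
           " nm for ", name, " (extrapolation is not allowed)")
    }
    wl <- wavelengths
    eps <- stats::approx(tab$wavelength_nm, tab$epsilon, xout = wavelengths,
                         rule = 1)$y
  }
  structure(list(name = name, wavelengths = wl, epsilon = eps),
            class = "chromophore_spectrum")
}

#' @export
print.chromophore_spectrum <- function(x, ...) {
  cat("<chromophore_spectrum>", x$name, "on", length(x$wavelengths),
      "wavelengths,", min(x$wavelengths), "-", max(x$wavelengths), "nm\n")
  invisible(x)
}

# Unit conventions: whole blood with 150 g/L hemoglobin defines 100 vol.%
# total hemoglobin; with a molar mass of 64,500 g/mol this is the molar
# hemoglobin concentration of undiluted blood.
.hb_g_per_L <- 150
.hb_molar_mass <- 64500
.hb_molarity <- .hb_g_per_L / .hb_molar_mass  # mol/L in whole blood

.new_absorption <- function(wavelengths, mu_a) {
  structure(list(wavelengths = wavelengths, mu_a = mu_a),
            class = "absorption_spectrum")
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  cat("<absorption_spectrum> on", length(x$wavelengths), "wavelengths,",
      "mu_a range", signif(min(x$mu_a), 4), "-", signif(max(x$mu_a), 4),
      "mm^-1\n")
  invisible(x)
}

#' Absorption coefficient of a hemoglobin derivative at a blood volume
#' concentration
#'
#' Converts a molar extinction spectrum to an absorption coefficient
#' mu_a(lambda) in mm^-1 for blood at `c_vol` volume percent, using the
#' convention that 100 vol.% blood carries 150 g/L hemoglobin (molar mass
#' 64,500 g/mol):
#' mu_a = ln(10) * epsilon * (150/64500) * (c_vol/100) / 10.
#'
#' @param spectrum A `chromophore_spectrum` for `"metHb"`, `"HbO"` or
#'   `"HbR"`.
#' @param c_vol Blood volume concentration in vol.% (0-100).
#' @return An `absorption_spectrum` (wavelengths nm, `mu_a` in mm^-1).
#' @export
hemoglobin_mu_a <- function(spectrum, c_vol) {
  stopifnot(inherits(spectrum, "chromophore_spectrum"))
  if (spectrum$name == "melanin") {
    stop("hemoglobin_mu_a() applies to hemoglobin derivatives; use melanin_mu_a()")
  }
  if (!is.numeric(c_vol) || length(c_vol) != 1L || is.na(c_vol) || c_vol < 0) {
    stop("c_vol must be a single non-negative number (vol.%)")
  }
  if (c_vol > 100) stop("c_vol exceeds 100 vol.%")
  # ln(10)*eps*M gives cm^-1; /10 converts to mm^-1
  mu_cm <- log(10) * spectrum$epsilon * .hb_molarity * (c_vol / 100)
  .new_absorption(spectrum$wavelengths, mu_cm / 10)
}

#' Total-hemoglobin absorption coefficient
#'
#' Sum of the metHb, HbO and HbR absorption coefficients; total hemoglobin
#' here includes the dysfunctional methemoglobin component.
#'
#' @param c_metHb,c_HbO,c_HbR Component blood volume concentrations, vol.%.
#' @param wavelengths Wavelength grid (nm); defaults to the analysis grid.
#' @return An `absorption_spectrum` for mu_a,HbT(lambda), mm^-1.
#' @export
total_hemoglobin_mu_a <- function(c_metHb, c_HbO, c_HbR,
                                  wavelengths = wavelength_grid("analysis")) {
  parts <- Map(function(name, c_vol) {
    hemoglobin_mu_a(load_extinction(name, wavelengths), c_vol)
  }, c("metHb", "HbO", "HbR"), list(c_metHb, c_HbO, c_HbR))
  .new_absorption(wavelengths, Reduce(`+`, lapply(parts, `[[`, "mu_a")))
}

#' Epidermal melanin absorption coefficient
#'
#' Melanin concentration is interpreted as the melanosome volume fraction
#' of the epidermis; the bundled melanosome absorption spectrum is scaled
#' linearly by that fraction.
#'
#' @param c_m Melanosome volume fraction of the epidermis, vol.% (0-100).
#' @param wavelengths Wavelength grid (nm); defaults to the analysis grid.
#' @return An `absorption_spectrum` for mu_a,m(lambda), mm^-1.
#' @export
melanin_mu_a <- function(c_m, wavelengths = wavelength_grid("analysis")) {
  if (!is.numeric(c_m) || length(c_m) != 1L || is.na(c_m) || c_m < 0) {
    stop("c_m must be a single non-negative number (vol.%)")
  }
  if (c_m > 100) stop("c_m exceeds 100 vol.%")
  mel <- load_extinction("melanin", wavelengths)
  .new_absorption(wavelengths, mel$epsilon * (c_m / 100))
}
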