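#' Absorbance regression and chromophore estimation
#'
#' The per-pixel inversion runs in two stages. MRA1 regresses the
#' absorbance spectrum A(lambda) = log10(1/r) on the four extinction
#' spectra plus an intercept over the 16-point analysis grid; the
#' intercept absorbs the scattering pseudo-attenuation, and the four slope
#' coefficients absorb the (wavelength-averaged) products of concentration
#' and mean optical path length. The second stage maps those five
#' regression coefficients to concentrations through empirical polynomial
#' formulae fitted on Monte Carlo-simulated spectra (see [fit_mra2()]).
#'
#' @name inverse
NULL

# reflectance floor applied before the log; reconstructed reflectance can
# reach zero after clipping
.reflectance_floor <- 1e-4

#' Absorbance spectrum from diffuse reflectance
#'
#' A(lambda) = log10(1 / r(lambda)). Reflectance values below a floor of
#' 1e-4 are raised to the floor (the Wiener output may be clipped at
#' zero); the number of floored values is attached as attribute
#' `"floored"`.
#'
#' @param r Reflectance values (vector or matrix, spectra in columns).
#' @return Absorbance of the same shape.
#' @export
absorbance <- function(r) {
  if (any(!is.finite(r))) stop("reflectance must be finite")
  if (any(r < 0)) stop("reflectance must be non-negative")
  floored <- sum(r < .reflectance_floor)
  r <- pmax(r, .reflectance_floor)
  out <- log10(1 / r)
  attr(out, "floored") <- floored
  out
}

#' MRA1 design matrix
#'
#' Columns: epsilon_metHb, epsilon_HbO, epsilon_HbR, epsilon_m and the
#' intercept, evaluated on the analysis grid.
#'
#' @param wavelengths Analysis wavelengths, nm.
#' @return Matrix length(wavelengths) x 5.
#' @export
mra1_design <- function(wavelengths = wavelength_grid("analysis")) {
  X <- cbind(
    metHb = load_extinction("metHb", wavelengths)$epsilon,
    HbO = load_extinction("HbO", wavelengths)$epsilon,
    HbR = load_extinction("HbR", wavelengths)$epsilon,
    m = load_extinction("melanin", wavelengths)$epsilon,
    intercept = 1)
  X
}

#' MRA1 projection operator
#'
#' The least-squares solve with the fixed design X reduces to a single
#' 5 x 16 matrix P = (X^T X)^-1 X^T, so whole-image regression is one
#' matrix product. An error is raised if the extinction spectra are
#' numerically collinear on the grid.
#'
#' @param wavelengths Analysis wavelengths, nm.
#' @return Matrix 5 x length(wavelengths) with rownames
#'   `a_metHb, a_HbO, a_HbR, a_m, a_0`.
#' @export
mra1_projection <- function(wavelengths = wavelength_grid("analysis")) {
  X <- mra1_design(wavelengths)
  # scale columns for conditioning check only
  Xs <- sweep(X, 2, apply(abs(X), 2, max), "/")
  kap <- kappa(Xs, exact = TRUE)
  if (kap > 1e10) {
    stop("extinction spectra are collinear on this grid (condition number ",
         format(kap, digits = 3), ")")
  }
  P <- solve(crossprod(X), t(X))
  rownames(P) <- c("a_metHb", "a_HbO", "a_HbR", "a_m", "a_0")
  P
}

#' First-stage multiple regression (MRA1)
#'
#' Ordinary least squares of the absorbance spectrum on the four
#' extinction spectra plus intercept.
#'
#' @param A Absorbance values on `wavelengths` (vector, or matrix with
#'   one spectrum per column).
#' @param wavelengths Analysis wavelengths, nm.
#' @return For a vector input, an `mra1_coefficients` object: named
#'   numeric `a_metHb, a_HbO, a_HbR, a_m, a_0` with attribute
#'   `"residual_norm"`. For a matrix input, a 5 x n coefficient matrix.
#' @export
mra1 <- function(A, wavelengths = wavelength_grid("analysis")) {
  P <- mra1_projection(wavelengths)
  if (is.matrix(A)) {
    if (nrow(A) != ncol(P)) stop("A must have one row per wavelength")
    return(P %*% A)
  }
  if (length(A) != ncol(P)) {
    stop("A must have one value per analysis wavelength (",
         ncol(P), ")")
  }
  a <- drop(P %*% A)
  X <- mra1_design(wavelengths)
  res <- A - drop(X %*% a)
  structure(a, residual_norm = sqrt(sum(res^2)), class = "mra1_coefficients")
}

# quadratic feature map shared by fit_mra2() and estimate_concentrations():
# constant, 5 linear terms, 5 squares, 10 pairwise products -> z = 21
.mra2_feature_names <- local({
  base <- c("a_metHb", "a_HbO", "a_HbR", "a_m", "a_0")
  nm <- c("1", base, paste0(base, "^2"))
  for (i in 1:4) for (j in (i + 1):5) nm <- c(nm, paste0(base[i], "*", base[j]))
  nm
})

# a5: matrix n x 5 -> n x 21
.mra2_features <- function(a5, order = 2L) {
  a5 <- as.matrix(a5)
  if (ncol(a5) != 5L) stop("expected 5 MRA1 coefficients per record")
  out <- cbind(1, a5)
  if (order >= 2L) {
    out <- cbind(out, a5^2)
    for (i in 1:4) for (j in (i + 1):5) out <- cbind(out, a5[, i] * a5[, j])
  }
  colnames(out) <- if (order >= 2L) .mra2_feature_names
                   else .mra2_feature_names[1:6]
  out
}

#' Estimate chromophore concentrations from MRA1 coefficients
#'
#' Builds the polynomial feature vector from the five MRA1 coefficients
#' and applies the four empirical coefficient vectors of the inverse
#' model. Derived quantities: C_HbT = C_metHb + C_HbO + C_HbR (total
#' hemoglobin includes the methemoglobin component) and StO2 =
#' 100 * C_HbO / C_HbT (NA when C_HbT <= 0). Estimates are clipped to
#' [0, 100] with the unclipped values preserved.
#'
#' @param coefs An `mra1_coefficients` object (or named numeric of length
#'   5 in the order a_metHb, a_HbO, a_HbR, a_m, a_0).
#' @param model An `empirical_inverse_model` from [fit_mra2()].
#' @return A `chromophore_estimate`: list with `C_metHb`, `C_HbO`,
#'   `C_HbR`, `C_m`, `C_HbT` (vol.%), `StO2` (%), `raw` (unclipped
#'   values) and `clipped` (logical flags).
#' @export
estimate_concentrations <- function(coefs, model) {
  stopifnot(inherits(model, "empirical_inverse_model"))
  a5 <- matrix(as.numeric(coefs)[1:5], 1, 5)
  feats <- .mra2_features(a5, model$order)
  if (ncol(feats) != ncol(model$b)) {
    stop("feature length ", ncol(feats), " does not match model z = ",
         ncol(model$b))
  }
  raw <- drop(model$b %*% t(feats))
  names(raw) <- rownames(model$b)
  clipped <- raw < 0 | raw > 100
  conc <- pmin(pmax(raw, 0), 100)
  hbt <- conc[["C_metHb"]] + conc[["C_HbO"]] + conc[["C_HbR"]]
  sto2 <- if (hbt > 0) 100 * conc[["C_HbO"]] / hbt else NA_real_
  structure(list(C_metHb = conc[["C_metHb"]], C_HbO = conc[["C_HbO"]],
                 C_HbR = conc[["C_HbR"]], C_m = conc[["C_m"]],
                 C_HbT = hbt, StO2 = sto2, raw = raw, clipped = clipped),
            class = "chromophore_estimate")
}

#' @export
print.chromophore_estimate <- function(x, ...) {
  cat(sprintf("<chromophore_estimate> metHb %.3f | HbO %.3f | HbR %.3f | m %.3f vol.%%; HbT %.3f; StO2 %s\n",
              x$C_metHb, x$C_HbO, x$C_HbR, x$C_m, x$C_HbT,
              if (is.na(x$StO2)) "NA" else sprintf("%.1f%%", x$StO2)))
  invisible(x)
}

#' Mixed arterio-venous oxygen saturation
#'
#' Volume-weighted mixture of arterial and venous saturation: with about
#' three quarters of blood volume residing on the venous side, skin tissue
#' oxygen saturation sits well below arterial SpO2 even in normoxia.
#'
#' @param sao2 Arterial oxygen saturation, % (0-100).
#' @param svo2 Venous oxygen saturation, % (0-100).
#' @param venous_fraction Venous fraction of blood volume, 0-1
#'   (default 0.75).
#' @return Mixed saturation, %.
#' @examples
#' mixed_saturation(98, 75, 0.75)  # 80.75
#' @export
mixed_saturation <- function(sao2, svo2, venous_fraction = 0.75) {
  if (sao2 < 0 || sao2 > 100 || svo2 < 0 || svo2 > 100) {
    stop("saturations must lie in [0, 100] %")
  }
  if (venous_fraction < 0 || venous_fraction > 1) {
    stop("venous_fraction must lie in [0, 1]")
  }
  venous_fraction * svo2 + (1 - venous_fraction) * sao2
}
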