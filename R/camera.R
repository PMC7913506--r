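#' Camera forward model and Wiener-estimation spectral reconstruction
#'
#' An RGB camera integrates the scene reflectance spectrum against three
#' channel responsivities: v_i = integral u_i(lambda) E(lambda) S(lambda)
#' r(lambda) dlambda, discretized as v = F r with F a 3 x 29 system
#' matrix. Wiener estimation inverts this 3 -> 29 projection in the
#' minimum-mean-squared-error sense using the second-order statistics
#' (autocorrelation) of a training ensemble of reflectance spectra:
#' r_hat = W v with W = <r r^T> F^T (F <r r^T> F^T + Sigma_noise)^-1.
#'
#' @name camera
NULL

#' Build a camera spectral model
#'
#' @param wavelengths Wavelength grid, nm (default: 29-point
#'   reconstruction grid).
#' @param u Matrix k x 3 of filter transmittances (columns: R, G, B).
#' @param E Illuminant spectrum, length k.
#' @param S Sensor sensitivity, length k.
#' @return A `camera_spectral_model` object.
#' @export
camera_spectral_model <- function(wavelengths, u, E, S) {
  assert_uniform_grid(wavelengths)
  u <- as.matrix(u)
  k <- length(wavelengths)
  if (nrow(u) != k || ncol(u) != 3L) stop("u must be a k x 3 matrix")
  if (length(E) != k || length(S) != k) stop("E and S must have length k")
  if (any(u < 0) || any(E < 0) || any(S < 0)) {
    stop("camera spectral curves must be non-negative")
  }
  structure(list(wavelengths = wavelengths, u = u, E = E, S = S),
            class = "camera_spectral_model")
}

#' Default camera profile
#'
#' Manufacturer spectral curves for a specific camera are deployment
#' inputs; the bundled default is a generic three-channel model with
#' Gaussian passbands centered at 610 (R), 540 (G) and 460 (B) nm, 60 nm
#' FWHM, flat illuminant and flat sensitivity. Any realistic profile can
#' be substituted via [camera_spectral_model()] or [read_camera_profile()].
#'
#' @param wavelengths Wavelength grid, nm.
#' @param centers Channel centers (R, G, B), nm.
#' @param fwhm Full width at half maximum of each passband, nm.
#' @return A `camera_spectral_model`.
#' @export
default_camera_model <- function(wavelengths = wavelength_grid("reconstruction"),
                                 centers = c(610, 540, 460), fwhm = 60) {
  sdev <- fwhm / (2 * sqrt(2 * log(2)))
  u <- sapply(centers, function(c0) exp(-(wavelengths - c0)^2 / (2 * sdev^2)))
  camera_spectral_model(wavelengths, u, rep(1, length(wavelengths)),
                        rep(1, length(wavelengths)))
}

#' Read a camera profile from CSV
#'
#' Expected columns: `wavelength_nm, u1, u2, u3, E, S` (u1..u3 = R, G, B
#' filter transmittances). Comment lines start with `#`. The profile is
#' linearly interpolated onto `wavelengths`.
#'
#' @param path CSV file path.
#' @param wavelengths Target grid, nm.
#' @return A `camera_spectral_model`.
#' @export
read_camera_profile <- function(path,
                                wavelengths = wavelength_grid("reconstruction")) {
  tab <- read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "u1", "u2", "u3", "E", "S")
  if (!all(need %in% names(tab))) {
    stop("camera profile must have columns: ", paste(need, collapse = ", "))
  }
  res <- sapply(c("u1", "u2", "u3", "E", "S"), function(col) {
    stats::approx(tab$wavelength_nm, tab[[col]], xout = wavelengths, rule = 1)$y
  })
  if (anyNA(res)) stop("camera profile does not cover the requested grid")
  camera_spectral_model(wavelengths, res[, 1:3], res[, "E"], res[, "S"])
}

#' Camera system matrix
#'
#' Discretization of the channel integrals: row i of F is
#' u_i(lambda) * E(lambda) * S(lambda) * dlambda.
#'
#' @param model A `camera_spectral_model`.
#' @return A 3 x k matrix.
#' @export
system_matrix <- function(model) {
  stopifnot(inherits(model, "camera_spectral_model"))
  dl <- diff(model$wavelengths)[1]
  F_ <- t(model$u * (model$E * model$S)) * dl
  rownames(F_) <- c("R", "G", "B")
  F_
}

#' Training ensemble of reflectance spectra
#'
#' @param spectra Matrix n x k, one reflectance spectrum per row, values
#'   in `[0, 1]`.
#' @param wavelengths Wavelength grid of the columns.
#' @return A `training_ensemble` object.
#' @export
training_ensemble <- function(spectra,
                              wavelengths = wavelength_grid("reconstruction")) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 1L) stop("ensemble must contain at least one spectrum")
  if (ncol(spectra) != length(wavelengths)) {
    stop("spectra must have one column per wavelength (", length(wavelengths), ")")
  }
  if (any(spectra < -1e-9) || any(spectra > 1 + 1e-9)) {
    stop("reflectance values must lie in [0, 1]")
  }
  structure(list(spectra = spectra, wavelengths = wavelengths,
                 count = nrow(spectra)), class = "training_ensemble")
}

#' Read a training ensemble from CSV
#'
#' Expected layout: first column `wavelength_nm`, remaining columns one
#' spectrum each (spectra stored column-wise for readability).
#'
#' @param path CSV file path.
#' @param wavelengths Target grid (spectra are interpolated).
#' @return A `training_ensemble`.
#' @export
read_ensemble <- function(path, wavelengths = wavelength_grid("reconstruction")) {
  tab <- read.csv(path, comment.char = "#")
  if (names(tab)[1] != "wavelength_nm") {
    stop("first column must be wavelength_nm")
  }
  sp <- sapply(tab[-1], function(col) {
    stats::approx(tab$wavelength_nm, col, xout = wavelengths, rule = 1)$y
  })
  training_ensemble(t(sp), wavelengths)
}

#' Ensemble autocorrelation matrix
#'
#' Mean over the ensemble of r r^T; symmetric positive semidefinite by
#' construction.
#'
#' @param ensemble A `training_ensemble`.
#' @return A k x k matrix.
#' @export
autocorrelation <- function(ensemble) {
  stopifnot(inherits(ensemble, "training_ensemble"))
  crossprod(ensemble$spectra) / ensemble$count
}

# Moore-Penrose pseudoinverse via SVD (used when the 3x3 core is singular)
.pinv <- function(m, tol = 1e-12) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Wiener estimation matrix
#'
#' W = A F^T (F A F^T + Sigma_n)^-1 where A is the ensemble
#' autocorrelation and Sigma_n an optional 3 x 3 camera-noise covariance
#' (default zero). A pseudoinverse is used if the 3 x 3 core is singular.
#'
#' @param acorr k x k autocorrelation matrix.
#' @param F_ 3 x k system matrix.
#' @param noise_cov Optional 3 x 3 noise covariance.
#' @return A k x 3 matrix W.
#' @export
wiener_matrix <- function(acorr, F_, noise_cov = NULL) {
  acorr <- as.matrix(acorr)
  F_ <- as.matrix(F_)
  if (nrow(F_) != 3L) stop("F must have 3 rows (RGB)")
  if (nrow(acorr) != ncol(acorr) || nrow(acorr) != ncol(F_)) {
    stop("autocorrelation must be k x k with k = ncol(F)")
  }
  if (max(abs(acorr - t(acorr))) > 1e-8 * max(1, max(abs(acorr)))) {
    stop("autocorrelation matrix must be symmetric")
  }
  core <- F_ %*% acorr %*% t(F_)
  if (!is.null(noise_cov)) {
    noise_cov <- as.matrix(noise_cov)
    if (!all(dim(noise_cov) == c(3L, 3L))) stop("noise_cov must be 3 x 3")
    core <- core + noise_cov
  }
  core_inv <- tryCatch(solve(core), error = function(e) .pinv(core))
  acorr %*% t(F_) %*% core_inv
}

#' Train a Wiener spectral-reconstruction model
#'
#' Combines the camera system matrix, optional white-balance
#' normalization, and the ensemble autocorrelation into the estimation
#' matrix. With `white_balance = TRUE` (the default) camera responses are
#' divided channelwise by the response to a standard white diffuser of
#' reflectance `white_reflectance`, and W is built for those normalized
#' responses, matching how images are acquired.
#'
#' @param ensemble A `training_ensemble` on the reconstruction grid.
#' @param camera A `camera_spectral_model`.
#' @param noise_cov Optional 3 x 3 response-noise covariance (in
#'   white-balanced units if `white_balance` is on).
#' @param white_balance Logical.
#' @param white_reflectance Reflectance of the white standard (0.99).
#' @return A `wiener_model` with elements `F` (effective system matrix in
#'   the response units used), `W`, `wavelengths`, `white_gain`.
#' @export
wiener_train <- function(ensemble, camera = default_camera_model(),
                         noise_cov = NULL, white_balance = TRUE,
                         white_reflectance = 0.99) {
  stopifnot(inherits(ensemble, "training_ensemble"))
  if (!isTRUE(all.equal(ensemble$wavelengths, camera$wavelengths))) {
    stop("ensemble and camera must share one wavelength grid")
  }
  F_raw <- system_matrix(camera)
  if (white_balance) {
    v_white <- as.vector(F_raw %*% rep(white_reflectance,
                                       length(camera$wavelengths)))
    if (any(v_white <= 0)) stop("white reference response must be positive")
    gain <- 1 / v_white
  } else {
    gain <- rep(1, 3)
  }
  F_eff <- F_raw * gain  # row-wise scaling
  W <- wiener_matrix(autocorrelation(ensemble), F_eff, noise_cov)
  structure(list(F = F_eff, W = W, wavelengths = camera$wavelengths,
                 white_gain = gain, white_balance = white_balance),
            class = "wiener_model")
}

#' @export
print.wiener_model <- function(x, ...) {
  cat("<wiener_model>", ncol(x$F), "spectral channels,",
      if (x$white_balance) "white-balanced" else "raw", "responses\n")
  invisible(x)
}

#' Wiener reconstruction of reflectance spectra from RGB
#'
#' Applies r_hat = W v per pixel. Accepts a length-3 response vector, a
#' 3 x n response matrix, or an H x W x 3 image array. Reconstructed
#' reflectance is clipped to `[0, 1]`; the fraction of clipped values is
#' attached as attribute `"clipped_fraction"` and a warning is raised when
#' it exceeds 1%.
#'
#' @param v RGB responses (white-balance-normalized if the model was
#'   trained that way).
#' @param model A `wiener_model`.
#' @param clip Logical; clip output to `[0, 1]` (default TRUE).
#' @return Length-29 spectrum, 29 x n matrix, or H x W x 29 array.
#' @export
reconstruct <- function(v, model, clip = TRUE) {
  stopifnot(inherits(model, "wiener_model"))
  k <- nrow(model$W)
  as_image <- is.array(v) && length(dim(v)) == 3L
  if (as_image) {
    d <- dim(v)
    if (d[3] != 3L) stop("image must have 3 channels")
    vm <- t(matrix(v, d[1] * d[2], 3L))
  } else if (is.matrix(v)) {
    if (nrow(v) != 3L) stop("response matrix must be 3 x n")
    vm <- v
  } else {
    if (length(v) != 3L) stop("response vector must have 3 elements")
    vm <- matrix(v, 3L, 1L)
  }
  if (any(vm < -1e-9)) stop("camera responses must be non-negative")
  r <- model$W %*% vm
  clipped <- 0
  if (clip) {
    clipped <- mean(r < 0 | r > 1)
    if (clipped > 0.01) {
      warning(sprintf("%.1f%% of reconstructed reflectance values clipped",
                      100 * clipped))
    }
    r[r < 0] <- 0
    r[r > 1] <- 1
  }
  out <- if (as_image) {
    array(t(r), c(dim(v)[1], dim(v)[2], k))
  } else if (is.matrix(v)) r else as.vector(r)
  attr(out, "clipped_fraction") <- clipped
  out
}
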