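#' Calibration of the empirical inverse model on simulated spectra
#'
#' The forward Monte Carlo model is evaluated over a grid of skin states:
#' epidermal melanin 1-10 vol.% (step 1), dermal total hemoglobin 0.2-1.0
#' vol.% (step 0.2), and 31 oxygenation/methemoglobin states per cell
#' (1550 spectra in total at the default grid). Each simulated spectrum is
#' regressed by MRA1, and the second-stage regression (MRA2) fits
#' polynomial formulae mapping the five MRA1 coefficients to the true
#' concentrations.
#'
#' @name calibration
NULL

#' Calibration grid specification
#'
#' The 31 default oxygenation states per (C_m, C_HbT) cell are the cross
#' of methemoglobin fraction f in {0, 0.25, 0.5} (fraction of total
#' hemoglobin) with functional oxygen saturation s in {0, 0.1, ..., 1}
#' (fraction of the remaining, functional hemoglobin that is oxygenated),
#' minus the two fully-oxygenated states with f > 0 (33 - 2 = 31; full
#' functional oxygenation during overt methemoglobinemia is not part of
#' the calibrated world). Pass `complete = TRUE` to [build_dataset()] to
#' keep all 33 states per cell, which makes the grid a complete tensor
#' (needed by the phantom interpolator).
#'
#' @param c_m_values Epidermal melanin concentrations, vol.%.
#' @param c_hbt_values Dermal total hemoglobin concentrations, vol.%.
#' @param sto2_values Functional oxygen saturation levels, % (0-100).
#' @param methb_fraction_values Methemoglobin fractions of total
#'   hemoglobin, 0-1.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(c_m_values = 1:10,
                      c_hbt_values = seq(0.2, 1.0, by = 0.2),
                      sto2_values = seq(0, 100, by = 10),
                      methb_fraction_values = c(0, 0.25, 0.5)) {
  stopifnot(all(c_m_values >= 0), all(c_m_values <= 100),
            all(c_hbt_values >= 0), all(c_hbt_values <= 100),
            all(sto2_values >= 0), all(sto2_values <= 100),
            all(methb_fraction_values >= 0), all(methb_fraction_values <= 1))
  structure(list(c_m_values = sort(unique(c_m_values)),
                 c_hbt_values = sort(unique(c_hbt_values)),
                 sto2_values = sort(unique(sto2_values)),
                 methb_fraction_values = sort(unique(methb_fraction_values))),
            class = "grid_spec")
}

#' Enumerate calibration states
#'
#' @param grid A [grid_spec()].
#' @param complete Keep the fully oxygenated states with methemoglobin
#'   fraction > 0 (complete tensor grid) instead of trimming them.
#' @return Data frame with one row per state: `c_m`, `c_hbt`,
#'   `methb_frac`, `s_func` (functional saturation, 0-1), component
#'   concentrations `c_metHb`, `c_HbO`, `c_HbR` (vol.%) and the true
#'   tissue oxygen saturation `sto2` = 100 * C_HbO / C_HbT.
#' @export
enumerate_states <- function(grid = grid_spec(), complete = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  s_func <- grid$sto2_values / 100
  states <- expand.grid(s_func = s_func,
                        methb_frac = grid$methb_fraction_values,
                        c_hbt = grid$c_hbt_values,
                        c_m = grid$c_m_values,
                        KEEP.OUT.ATTRS = FALSE)
  if (!complete) {
    # trim the fully oxygenated functional-hemoglobin states with f > 0
    states <- states[!(states$methb_frac > 0 &
                       states$s_func >= 1 - 1e-12), , drop = FALSE]
  }
  states$c_metHb <- states$methb_frac * states$c_hbt
  states$c_HbO <- states$s_func * (1 - states$methb_frac) * states$c_hbt
  states$c_HbR <- states$c_hbt - states$c_metHb - states$c_HbO
  states$sto2 <- ifelse(states$c_hbt > 0, 100 * states$c_HbO / states$c_hbt, NA)
  rownames(states) <- NULL
  states[, c("c_m", "c_hbt", "methb_frac", "s_func",
             "c_metHb", "c_HbO", "c_HbR", "sto2")]
}

#' Build the calibration dataset
#'
#' Simulates one diffuse reflectance spectrum per grid state and runs
#' MRA1 on the analysis-band restriction of each spectrum.
#'
#' Two simulation routes are available. `"direct"` launches an
#' independent Monte Carlo run per state and wavelength (the
#' reference-fidelity route; the full default grid at 5e6 packets per
#' wavelength is a long compute). `"pathlength"` simulates the shared
#' scattering geometry once per wavelength with zero absorption and
#' rescales the recorded trajectories per state by continuous absorption
#' weighting (see [mc_pathlength_library()]); this is unbiased, uses
#' common random numbers across states, and makes desk-scale calibration
#' feasible, so it is the default.
#'
#' @param grid A [grid_spec()].
#' @param mc An [mc_config()]; `n_photons` is per wavelength.
#' @param method `"pathlength"` or `"direct"`.
#' @param spectral_grid `"analysis"` (16 channels) or `"reconstruction"`
#'   (29 channels; the analysis subset is used for MRA1).
#' @param scattering A [scattering_model()].
#' @param complete Passed to [enumerate_states()].
#' @param d_epi,d_derm,n Geometry as in [skin_tissue()].
#' @return A `calibration_dataset`: list with `records` (the state table
#'   plus MRA1 coefficients `a_metHb ... a_0`), `spectra` (n_states x k
#'   reflectance matrix), `wavelengths`, `method`, `complete`, `grid`.
#' @export
build_dataset <- function(grid = grid_spec(), mc = mc_config(),
                          method = c("pathlength", "direct"),
                          spectral_grid = c("analysis", "reconstruction"),
                          scattering = scattering_model(),
                          complete = FALSE,
                          d_epi = 0.06, d_derm = 4.94, n = 1.4) {
  method <- match.arg(method)
  spectral_grid <- match.arg(spectral_grid)
  wl <- wavelength_grid(spectral_grid)
  states <- enumerate_states(grid, complete = complete)
  n_states <- nrow(states)
  if (n_states < 1L) stop("empty calibration grid")

  mel_eps <- load_extinction("melanin", wl)$epsilon
  spectra <- matrix(NA_real_, n_states, length(wl))
  if (method == "pathlength") {
    lib <- mc_pathlength_library(wl, scattering, mc, d_epi, d_derm, n)
    for (i in seq_len(n_states)) {
      st <- states[i, ]
      mua_epi <- mel_eps * (st$c_m / 100)
      mua_derm <- total_hemoglobin_mu_a(st$c_metHb, st$c_HbO, st$c_HbR, wl)$mu_a
      spectra[i, ] <- reflectance_from_pathlengths(lib, mua_epi, mua_derm)
    }
  } else {
    for (i in seq_len(n_states)) {
      st <- states[i, ]
      builder <- skin_tissue(st$c_metHb, st$c_HbO, st$c_HbR, st$c_m,
                             scattering, d_epi, d_derm, n)
      cfg <- mc
      cfg$seed <- .derive_seed(mc$seed, 1000 + i)
      sp <- tryCatch(simulate_spectrum(builder, wl, cfg), error = function(e) {
        stop("Monte Carlo failed at grid point (c_m=", st$c_m, ", c_hbt=",
             st$c_hbt, ", f=", st$methb_frac, ", s=", st$s_func, "): ",
             conditionMessage(e))
      })
      spectra[i, ] <- sp$reflectance
    }
  }
  colnames(spectra) <- paste0("r_", wl)

  # MRA1 on the analysis band
  idx <- if (spectral_grid == "reconstruction") analysis_indices()
         else seq_along(wl)
  A <- absorbance(t(spectra[, idx, drop = FALSE]))
  coefs <- t(mra1(A))  # n x 5
  colnames(coefs) <- c("a_metHb", "a_HbO", "a_HbR", "a_m", "a_0")

  structure(list(records = cbind(states, as.data.frame(coefs)),
                 spectra = spectra, wavelengths = wl, method = method,
                 complete = complete, grid = grid,
                 scattering = scattering),
            class = "calibration_dataset")
}

#' @export
print.calibration_dataset <- function(x, ...) {
  cat("<calibration_dataset>", nrow(x$records), "records,",
      length(x$wavelengths), "wavelengths (", x$method, "simulation )\n")
  invisible(x)
}

#' Recalibrate MRA1 coefficients through a camera model
#'
#' Replaces each record's MRA1 coefficients with those obtained after
#' pushing the simulated spectrum through the camera forward model and
#' Wiener reconstruction (r -> v = F r -> r_hat = W v), i.e. through the
#' identical channel the pipeline applies to measured images. Fitting the
#' second-stage regression on these camera-consistent coefficients keeps
#' the empirical formulae on the same coefficient manifold that real
#' reconstructed spectra occupy; fitting on raw-spectrum coefficients and
#' applying to reconstructed spectra extrapolates off that manifold and
#' can corrupt the methemoglobin estimate even at reconstruction GFC
#' above 0.9999. Use together with
#' `fit_mra2(..., rank_action = "minnorm")`.
#'
#' @param dataset A `calibration_dataset` built on the reconstruction
#'   grid (`spectral_grid = "reconstruction"`).
#' @param wiener A `wiener_model` on the same grid.
#' @return The dataset with updated coefficient columns and a
#'   `camera_consistent` flag.
#' @export
reproject_dataset <- function(dataset, wiener) {
  stopifnot(inherits(dataset, "calibration_dataset"),
            inherits(wiener, "wiener_model"))
  if (!isTRUE(all.equal(dataset$wavelengths,
                        wavelength_grid("reconstruction")))) {
    stop("reprojection requires a dataset on the 29-point reconstruction grid")
  }
  v <- wiener$F %*% t(dataset$spectra)
  r_hat <- reconstruct(v, wiener)
  A <- absorbance(r_hat[analysis_indices(), , drop = FALSE])
  coefs <- t(mra1(A))
  colnames(coefs) <- c("a_metHb", "a_HbO", "a_HbR", "a_m", "a_0")
  dataset$records[, colnames(coefs)] <- coefs
  dataset$camera_consistent <- TRUE
  dataset
}

#' Persist / restore a calibration dataset as CSV
#'
#' One row per record: state columns, reflectances `r_<wl>`, MRA1
#' coefficients. The simulation metadata are stored in `#` header lines.
#'
#' @param dataset A `calibration_dataset`.
#' @param path Output CSV path.
#' @export
write_calibration_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  tab <- cbind(dataset$records, as.data.frame(dataset$spectra))
  hdr <- c("# hemospect calibration dataset v1",
           paste0("# method: ", dataset$method),
           paste0("# complete: ", dataset$complete),
           paste0("# wavelengths_nm: ",
                  paste(dataset$wavelengths, collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_dataset
#' @return `read_calibration_dataset()` returns the restored
#'   `calibration_dataset` (without the scattering model closure).
#' @export
read_calibration_dataset <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  wl_line <- hdr[grepl("wavelengths_nm:", hdr)]
  wl <- as.numeric(strsplit(sub(".*wavelengths_nm: *", "", wl_line),
                            " ")[[1]])
  method <- sub(".*method: *", "", hdr[grepl("# method:", hdr)])
  complete <- as.logical(sub(".*complete: *", "",
                             hdr[grepl("# complete:", hdr)]))
  tab <- read.csv(path, comment.char = "#")
  rcols <- paste0("r_", wl)
  spectra <- as.matrix(tab[, rcols, drop = FALSE])
  records <- tab[, setdiff(names(tab), rcols), drop = FALSE]
  structure(list(records = records, spectra = spectra, wavelengths = wl,
                 method = method, complete = complete, grid = NULL,
                 scattering = NULL),
            class = "calibration_dataset")
}

# exact back-transform of OLS coefficients fitted on standardized features
.ols_standardized <- function(feats, y, rank_action = "error") {
  mu <- colMeans(feats)
  sdv <- apply(feats, 2, stats::sd)
  const <- sdv < 1e-12
  fs <- feats
  fs[, !const] <- sweep(sweep(feats[, !const, drop = FALSE], 2, mu[!const]),
                        2, sdv[!const], "/")
  fs[, const] <- 1
  q <- qr(fs)
  if (q$rank < ncol(fs)) {
    if (rank_action == "error") {
      stop("rank-deficient MRA2 design (rank ", q$rank, " < ", ncol(fs),
           "); try a lower polynomial order or a larger grid")
    }
    # minimum-norm least squares via SVD (coefficients of camera-projected
    # spectra live on a low-dimensional manifold; see fit_mra2 docs)
    s <- svd(fs)
    keep <- s$d > 1e-10 * s$d[1]
    bs <- drop(s$v[, keep, drop = FALSE] %*%
                 ((t(s$u[, keep, drop = FALSE]) %*% y) / s$d[keep]))
    names(bs) <- colnames(fs)
  } else {
    bs <- qr.coef(q, y)
  }
  b <- numeric(ncol(feats))
  b[!const] <- bs[!const] / sdv[!const]
  b[const] <- sum(bs[const]) - sum(bs[!const] * mu[!const] / sdv[!const])
  fit <- drop(feats %*% b)
  list(b = b, r_squared = 1 - sum((y - fit)^2) / sum((y - mean(y))^2))
}

#' Fit the second-stage regression (MRA2)
#'
#' For each chromophore, ordinary least squares of the true concentration
#' on the polynomial feature vector built from the five MRA1 coefficients.
#' The default feature set (order 2) is the constant, the five linear
#' terms, their five squares and the ten pairwise products (z = 21).
#'
#' When the dataset has been passed through a camera model
#' ([reproject_dataset()]), the MRA1 coefficients live on a
#' low-dimensional manifold (an RGB response has only three degrees of
#' freedom) and the quadratic design is rank-deficient by construction;
#' `rank_action = "minnorm"` then fits the minimum-norm least-squares
#' solution via SVD instead of erroring.
#'
#' @param dataset A `calibration_dataset` (or its `records` data frame).
#' @param order Polynomial order, 1 or 2 (default 2).
#' @param rank_action `"error"` (default) or `"minnorm"`.
#' @return An `empirical_inverse_model`: list with `b` (4 x z coefficient
#'   matrix, rows `C_metHb, C_HbO, C_HbR, C_m`), `order`, `z`,
#'   `feature_names`, `r_squared` and `n_records`.
#' @export
fit_mra2 <- function(dataset, order = 2L,
                     rank_action = c("error", "minnorm")) {
  rank_action <- match.arg(rank_action)
  records <- if (inherits(dataset, "calibration_dataset")) dataset$records
             else as.data.frame(dataset)
  order <- as.integer(order)
  stopifnot(order %in% c(1L, 2L))
  acols <- c("a_metHb", "a_HbO", "a_HbR", "a_m", "a_0")
  if (!all(acols %in% names(records))) {
    stop("records must contain MRA1 coefficient columns ",
         paste(acols, collapse = ", "))
  }
  feats <- .mra2_features(as.matrix(records[, acols]), order)
  if (nrow(feats) <= ncol(feats)) {
    stop("need more than z = ", ncol(feats), " records to fit MRA2")
  }
  targets <- c(C_metHb = "c_metHb", C_HbO = "c_HbO", C_HbR = "c_HbR",
               C_m = "c_m")
  fits <- lapply(targets, function(col) {
    .ols_standardized(feats, records[[col]], rank_action)
  })
  b <- do.call(rbind, lapply(fits, `[[`, "b"))
  rownames(b) <- names(targets)
  colnames(b) <- colnames(feats)
  structure(list(b = b, order = order, z = ncol(feats),
                 feature_names = colnames(feats),
                 r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
                 n_records = nrow(feats)),
            class = "empirical_inverse_model")
}

#' @export
print.empirical_inverse_model <- function(x, ...) {
  cat("<empirical_inverse_model> order", x$order, ", z =", x$z,
      ", fitted on", x$n_records, "records\n")
  cat("  in-sample R^2:",
      paste(sprintf("%s %.4f", names(x$r_squared), x$r_squared),
            collapse = ", "), "\n")
  invisible(x)
}

#' Apply the empirical inverse model to MRA1 coefficient sets
#'
#' Vectorized companion of [estimate_concentrations()]: maps an n x 5
#' matrix of MRA1 coefficients to an n x 4 matrix of (unclipped)
#' concentration estimates.
#'
#' @param model An `empirical_inverse_model`.
#' @param a5 Matrix n x 5 (columns a_metHb, a_HbO, a_HbR, a_m, a_0).
#' @return Matrix n x 4 with columns `C_metHb, C_HbO, C_HbR, C_m`.
#' @export
predict_concentrations <- function(model, a5) {
  stopifnot(inherits(model, "empirical_inverse_model"))
  feats <- .mra2_features(a5, model$order)
  out <- feats %*% t(model$b)
  colnames(out) <- rownames(model$b)
  out
}

#' Save / load an empirical inverse model as JSON
#'
#' @param model An `empirical_inverse_model`.
#' @param path JSON file path.
#' @export
save_inverse_model <- function(model, path) {
  stopifnot(inherits(model, "empirical_inverse_model"))
  obj <- list(format = "hemospect_inverse_model_v1",
              order = model$order, z = model$z,
              feature_names = model$feature_names,
              r_squared = as.list(model$r_squared),
              n_records = model$n_records,
              b = setNames(lapply(seq_len(nrow(model$b)),
                                  function(i) unname(model$b[i, ])),
                           rownames(model$b)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_inverse_model
#' @export
read_inverse_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hemospect_inverse_model_v1")) {
    stop("not a hemospect inverse model file")
  }
  b <- do.call(rbind, obj$b)
  colnames(b) <- obj$feature_names
  structure(list(b = b, order = as.integer(obj$order), z = as.integer(obj$z),
                 feature_names = obj$feature_names,
                 r_squared = unlist(obj$r_squared),
                 n_records = obj$n_records),
            class = "empirical_inverse_model")
}

#' Leave-one-out closed-loop recovery
#'
#' For each record, the inverse model is refitted on the remaining
#' records and applied to the held-out MRA1 coefficients; estimates are
#' compared with the record's ground-truth concentrations. This is the
#' package's primary internal validity check of the calibrated pipeline.
#'
#' @param dataset A `calibration_dataset`.
#' @param order MRA2 polynomial order.
#' @param interior_only Restrict the summary to grid-interior records
#'   (states not on the boundary of any grid axis); default TRUE for the
#'   relative-error summary, consistent with how an interpolating
#'   empirical model is meant to be used.
#' @return A list with `estimates` (n x 4 matrix), `truth` (n x 4),
#'   `median_rel_error` (per chromophore, over interior records with
#'   truth > 0), `sto2_error` (estimated minus true StO2, percentage
#'   points, interior records) and `interior` (logical index).
#' @export
closed_loop_recovery <- function(dataset, order = 2L, interior_only = TRUE) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  rec <- dataset$records
  n <- nrow(rec)
  acols <- c("a_metHb", "a_HbO", "a_HbR", "a_m", "a_0")
  est <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("C_metHb", "C_HbO", "C_HbR", "C_m")))
  for (i in seq_len(n)) {
    fit <- fit_mra2(rec[-i, , drop = FALSE], order = order)
    est[i, ] <- predict_concentrations(fit, as.matrix(rec[i, acols]))
  }
  truth <- as.matrix(rec[, c("c_metHb", "c_HbO", "c_HbR", "c_m")])
  colnames(truth) <- colnames(est)

  axis_interior <- function(v) {
    r <- range(v)
    v > r[1] & v < r[2]
  }
  interior <- axis_interior(rec$c_m) & axis_interior(rec$c_hbt) &
    axis_interior(rec$s_func)
  use <- if (interior_only) interior else rep(TRUE, n)

  rel <- abs(est - truth) / ifelse(truth > 0, truth, NA)
  med <- apply(rel[use, , drop = FALSE], 2, stats::median, na.rm = TRUE)

  est_clip <- pmin(pmax(est, 0), 100)
  hbt_est <- rowSums(est_clip[, 1:3, drop = FALSE])
  sto2_est <- ifelse(hbt_est > 0, 100 * est_clip[, "C_HbO"] / hbt_est, NA)
  sto2_err <- sto2_est - rec$sto2

  list(estimates = est, truth = truth, median_rel_error = med,
       sto2_error = sto2_err[use], interior = interior)
}
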