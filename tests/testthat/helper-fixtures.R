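# Shared fixtures, built lazily once per test run and cached across files.
# Scale: the reduced calibration world (thinned grid, 1e4 photon packets per
# wavelength through the path-length library) that the acceptance criteria
# prescribe for desk-scale runs.

.fx <- new.env(parent = emptyenv())

fx_grid <- function() {
  grid_spec(c_m_values = c(1, 4, 7, 10),
            c_hbt_values = c(0.2, 0.4, 0.7, 1.0),
            sto2_values = seq(0, 100, by = 25))
}

fx_dataset_complete <- function() {
  if (is.null(.fx$ds_complete)) {
    .fx$ds_complete <- build_dataset(fx_grid(), mc_config(1e4, seed = 11),
                                     complete = TRUE,
                                     spectral_grid = "reconstruction")
  }
  .fx$ds_complete
}

# the trimmed (31-state-rule) dataset is a row subset of the complete one
fx_dataset <- function() {
  if (is.null(.fx$ds)) {
    ds <- fx_dataset_complete()
    keep <- !(ds$records$methb_frac > 0 & ds$records$s_func >= 1 - 1e-12)
    ds$records <- ds$records[keep, , drop = FALSE]
    ds$spectra <- ds$spectra[keep, , drop = FALSE]
    ds$complete <- FALSE
    .fx$ds <- ds
  }
  .fx$ds
}

fx_interp <- function() {
  if (is.null(.fx$interp)) .fx$interp <- forward_interpolator(fx_dataset_complete())
  .fx$interp
}

fx_wiener <- function() {
  if (is.null(.fx$wiener)) {
    ds <- fx_dataset_complete()
    .fx$wiener <- wiener_train(training_ensemble(ds$spectra, ds$wavelengths))
  }
  .fx$wiener
}

# paper-faithful inverse model (MRA2 on raw-spectrum coefficients)
fx_model <- function() {
  if (is.null(.fx$model)) .fx$model <- fit_mra2(fx_dataset())
  .fx$model
}

# camera-consistent inverse model used by the imaging pipeline
fx_model_cam <- function() {
  if (is.null(.fx$model_cam)) {
    .fx$model_cam <- fit_mra2(reproject_dataset(fx_dataset_complete(),
                                                fx_wiener()),
                              rank_action = "minnorm")
  }
  .fx$model_cam
}

fx_loo <- function() {
  if (is.null(.fx$loo)) .fx$loo <- closed_loop_recovery(fx_dataset())
  .fx$loo
}
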