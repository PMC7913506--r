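#' Synthetic phantom scenes
#'
#' Ground-truthed stand-ins for skin images: per-pixel chromophore maps
#' are pushed through the calibrated forward model (multilinear
#' interpolation of the simulated spectra library), projected to RGB by
#' the camera system matrix, white balanced, and corrupted with sensor
#' noise and quantization. Per-pixel Monte Carlo at image scale is not
#' desk-feasible; the library interpolation is the rendering route.
#'
#' @name phantom
NULL

# run expr with a local deterministic RNG state, restoring the caller's
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build a forward interpolator from a complete calibration dataset
#'
#' Requires a dataset built with `complete = TRUE` (full tensor grid) on
#' the 29-point reconstruction grid. Spectra are interpolated
#' multilinearly in the four state coordinates (C_m, C_HbT, methemoglobin
#' fraction, functional saturation); at grid nodes the interpolation
#' reproduces the library spectra exactly.
#'
#' @param dataset A `calibration_dataset` with `complete = TRUE` and
#'   `spectral_grid = "reconstruction"`.
#' @return A `forward_interpolator` object, callable through
#'   [interpolate_spectra()].
#' @export
forward_interpolator <- function(dataset) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  if (!isTRUE(dataset$complete)) {
    stop("forward interpolation needs a complete tensor grid; rebuild the ",
         "dataset with complete = TRUE")
  }
  rec <- dataset$records
  ax <- list(c_m = sort(unique(rec$c_m)),
             c_hbt = sort(unique(rec$c_hbt)),
             f = sort(unique(rec$methb_frac)),
             s = sort(unique(rec$s_func)))
  n_ax <- vapply(ax, length, integer(1))
  if (nrow(rec) != prod(n_ax)) {
    stop("dataset is not a complete tensor over its state axes")
  }
  key <- function(cm, hbt, f, s) {
    paste(match(cm, ax$c_m), match(hbt, ax$c_hbt), match(f, ax$f),
          match(s, ax$s))
  }
  idx <- integer(prod(n_ax))
  pos <- function(i1, i2, i3, i4) {
    ((i4 - 1L) * n_ax[3] * n_ax[2] * n_ax[1]) +
      ((i3 - 1L) * n_ax[2] * n_ax[1]) + ((i2 - 1L) * n_ax[1]) + i1
  }
  i1 <- match(rec$c_m, ax$c_m); i2 <- match(rec$c_hbt, ax$c_hbt)
  i3 <- match(rec$methb_frac, ax$f); i4 <- match(rec$s_func, ax$s)
  idx[pos(i1, i2, i3, i4)] <- seq_len(nrow(rec))
  if (any(idx == 0L)) stop("dataset grid has missing tensor cells")
  structure(list(axes = ax, n_ax = n_ax, idx = idx, pos = pos,
                 spectra = dataset$spectra,
                 wavelengths = dataset$wavelengths),
            class = "forward_interpolator")
}

# locate query values on one axis: cell index + fractional weight
.axis_locate <- function(x, ax, name) {
  eps <- 1e-9 * max(1, max(abs(ax)))
  if (any(x < min(ax) - eps) || any(x > max(ax) + eps)) {
    stop("phantom state outside the calibrated hull on axis '", name,
         "' (range ", min(ax), "-", max(ax), ")")
  }
  x <- pmin(pmax(x, min(ax)), max(ax))
  if (length(ax) == 1L) {
    return(list(i = rep(1L, length(x)), w = rep(0, length(x))))
  }
  i <- findInterval(x, ax, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(ax) - 1L)
  w <- (x - ax[i]) / (ax[i + 1L] - ax[i])
  list(i = i, w = w)
}

#' Interpolate forward-model reflectance spectra
#'
#' @param interp A [forward_interpolator()].
#' @param c_metHb,c_HbO,c_HbR,c_m Concentration vectors (vol.%), one
#'   entry per query state.
#' @return Matrix n x k of reflectance spectra on the library grid.
#' @export
interpolate_spectra <- function(interp, c_metHb, c_HbO, c_HbR, c_m) {
  stopifnot(inherits(interp, "forward_interpolator"))
  n <- length(c_m)
  stopifnot(length(c_metHb) == n, length(c_HbO) == n, length(c_HbR) == n)
  hbt <- c_metHb + c_HbO + c_HbR
  f <- ifelse(hbt > 0, c_metHb / hbt, 0)
  func <- c_HbO + c_HbR
  s <- ifelse(func > 0, c_HbO / func, 0)
  loc <- list(.axis_locate(c_m, interp$axes$c_m, "c_m"),
              .axis_locate(hbt, interp$axes$c_hbt, "c_hbt"),
              .axis_locate(f, interp$axes$f, "methb_frac"),
              .axis_locate(s, interp$axes$s, "s_func"))
  n_ax <- interp$n_ax
  out <- matrix(0, n, ncol(interp$spectra))
  for (corner in 0:15) {
    bits <- bitwAnd(bitwShiftR(corner, 0:3), 1L)
    wgt <- rep(1, n)
    ii <- vector("list", 4)
    for (a in 1:4) {
      up <- bits[a] == 1L
      ii[[a]] <- pmin(loc[[a]]$i + as.integer(up), n_ax[a])
      wa <- if (up) loc[[a]]$w else 1 - loc[[a]]$w
      wgt <- wgt * wa
    }
    nz <- wgt > 0
    if (!any(nz)) next
    rows <- interp$idx[interp$pos(ii[[1]][nz], ii[[2]][nz],
                                  ii[[3]][nz], ii[[4]][nz])]
    out[nz, ] <- out[nz, , drop = FALSE] +
      interp$spectra[rows, , drop = FALSE] * wgt[nz]
  }
  out
}

#' Define a phantom scene
#'
#' Concentration inputs may be scalars or matrices; scalars are expanded
#' to `dim`. The seed is mandatory: every rendered artifact must be
#' regenerable bit-identically.
#'
#' @param c_metHb,c_HbO,c_HbR,c_m Ground-truth concentration maps
#'   (vol.%), scalar or matrix.
#' @param dim Image size `c(height, width)` used when all inputs are
#'   scalar.
#' @param noise_sd Additive Gaussian camera noise, as a fraction of full
#'   scale (default 0.005).
#' @param bit_depth Quantization depth per channel (default 8).
#' @param seed Integer seed (required).
#' @return A `phantom_scene` object.
#' @export
phantom_scene <- function(c_metHb, c_HbO, c_HbR, c_m, dim = c(64, 64),
                          noise_sd = 0.005, bit_depth = 8L, seed) {
  if (missing(seed)) stop("phantom_scene requires an explicit seed")
  maps <- list(c_metHb = c_metHb, c_HbO = c_HbO, c_HbR = c_HbR, c_m = c_m)
  dims <- lapply(maps, function(m) if (is.matrix(m)) dim(m) else NULL)
  dims <- dims[!vapply(dims, is.null, logical(1))]
  if (length(dims) > 0) {
    dim <- dims[[1]]
    if (!all(vapply(dims, function(d) all(d == dim), logical(1)))) {
      stop("all concentration maps must share one dimension")
    }
  }
  maps <- lapply(maps, function(m) {
    if (is.matrix(m)) m else matrix(m, dim[1], dim[2])
  })
  if (any(unlist(maps) < 0)) stop("concentrations must be non-negative")
  structure(c(maps, list(dim = dim, noise_sd = noise_sd,
                         bit_depth = as.integer(bit_depth),
                         seed = as.integer(seed))),
            class = "phantom_scene")
}

#' Render a phantom scene to an RGB frame
#'
#' Per-pixel reflectance spectra are interpolated from the forward
#' library, projected through the (white-balanced) camera system matrix,
#' and degraded by additive Gaussian noise and quantization. The
#' spectral truth stack and the scene are returned alongside the frame.
#'
#' @param scene A [phantom_scene()].
#' @param interp A [forward_interpolator()] on the reconstruction grid.
#' @param wiener A `wiener_model` (its effective system matrix and white
#'   balance define the camera).
#' @param keep_spectra Attach the per-pixel true spectral stack
#'   (H x W x k array); default TRUE.
#' @return A `phantom_frame`: list `rgb` (H x W x 3, quantized
#'   white-balanced responses in [0, 1]), `truth` (the scene maps plus
#'   derived C_HbT and StO2), `spectra` (optional truth stack), `scene`.
#' @export
render_scene <- function(scene, interp, wiener, keep_spectra = TRUE) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(interp, "forward_interpolator"),
            inherits(wiener, "wiener_model"))
  if (!isTRUE(all.equal(interp$wavelengths, wiener$wavelengths))) {
    stop("interpolator and camera model must share one wavelength grid")
  }
  h <- scene$dim[1]; w <- scene$dim[2]
  # interpolate per unique state, then scatter to pixels
  states <- cbind(as.vector(scene$c_metHb), as.vector(scene$c_HbO),
                  as.vector(scene$c_HbR), as.vector(scene$c_m))
  uq <- unique(states)
  match_row <- match(apply(states, 1, paste, collapse = "\r"),
                     apply(uq, 1, paste, collapse = "\r"))
  sp_u <- interpolate_spectra(interp, uq[, 1], uq[, 2], uq[, 3], uq[, 4])
  sp <- sp_u[match_row, , drop = FALSE]            # P x k
  v <- wiener$F %*% t(sp)                          # 3 x P, white-balanced
  v <- .with_seed(scene$seed, {
    v + matrix(rnorm(length(v), sd = scene$noise_sd), nrow(v), ncol(v))
  })
  levels <- 2^scene$bit_depth - 1
  v <- round(pmin(pmax(v, 0), 1) * levels) / levels
  rgb <- array(t(v), c(h, w, 3L))

  hbt <- scene$c_metHb + scene$c_HbO + scene$c_HbR
  truth <- list(C_metHb = scene$c_metHb, C_HbO = scene$c_HbO,
                C_HbR = scene$c_HbR, C_m = scene$c_m, C_HbT = hbt,
                StO2 = ifelse(hbt > 0, 100 * scene$c_HbO / hbt, NA))
  out <- list(rgb = rgb, truth = truth, scene = scene)
  if (keep_spectra) out$spectra <- array(sp, c(h, w, ncol(sp)))
  structure(out, class = "phantom_frame")
}

#' Analytic peak time of the double-exponential pulse
#'
#' @param tau_rise,tau_decay Time constants, minutes (decay > rise).
#' @return Time of the pulse maximum, minutes.
#' @export
pulse_peak_time <- function(tau_rise, tau_decay) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise)
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}

#' Simulated methemoglobinemia time series
#'
#' Emulates the measurement structure of a nitrite-challenge experiment:
#' methemoglobin rises and recovers following a double-exponential pulse
#' h(t) = exp(-t/tau_decay) - exp(-t/tau_rise) (normalized to peak
#' `peak_methb` above baseline), while oxygenated hemoglobin is reduced
#' by the same amount so that total hemoglobin stays constant.
#'
#' @param baseline A [phantom_scene()] defining the pre-challenge state.
#' @param peak_methb Peak added methemoglobin, vol.%.
#' @param tau_rise,tau_decay Pulse time constants, minutes
#'   (`tau_decay > tau_rise`).
#' @param n_frames Number of frames.
#' @param dt Frame interval, minutes.
#' @param interp,wiener Passed to [render_scene()].
#' @param keep_spectra Passed to [render_scene()] (default FALSE for
#'   series).
#' @return A `phantom_series`: list `frames` (list of `phantom_frame`),
#'   `truth` (data frame: `frame`, `time_min`, `delta_c_metHb`, and the
#'   scene-mean concentrations per frame) and `peak_time` (analytic
#'   pulse maximum, minutes).
#' @export
methemoglobinemia_series <- function(baseline, peak_methb, tau_rise = 15,
                                     tau_decay = 90, n_frames = 24, dt = 15,
                                     interp, wiener, keep_spectra = FALSE) {
  stopifnot(inherits(baseline, "phantom_scene"),
            peak_methb >= 0, tau_rise > 0, tau_decay > tau_rise,
            n_frames >= 1)
  t <- (seq_len(n_frames) - 1) * dt
  h <- exp(-t / tau_decay) - exp(-t / tau_rise)
  tpk <- pulse_peak_time(tau_rise, tau_decay)
  hmax <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  dmet <- peak_methb * h / hmax
  if (any(baseline$c_HbO - max(dmet) < -1e-9)) {
    stop("peak_methb exceeds the available baseline C_HbO; total ",
         "hemoglobin could not be held constant")
  }
  frames <- vector("list", n_frames)
  means <- matrix(NA_real_, n_frames, 4,
                  dimnames = list(NULL,
                                  c("c_metHb", "c_HbO", "c_HbR", "c_m")))
  for (k in seq_len(n_frames)) {
    sc <- baseline
    sc$c_metHb <- baseline$c_metHb + dmet[k]
    sc$c_HbO <- baseline$c_HbO - dmet[k]
    sc$seed <- baseline$seed + k
    frames[[k]] <- render_scene(sc, interp, wiener,
                                keep_spectra = keep_spectra)
    means[k, ] <- c(mean(sc$c_metHb), mean(sc$c_HbO), mean(sc$c_HbR),
                    mean(sc$c_m))
  }
  truth <- data.frame(frame = seq_len(n_frames), time_min = t,
                      delta_c_metHb = dmet, means)
  structure(list(frames = frames, truth = truth, peak_time = tpk),
            class = "phantom_series")
}
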