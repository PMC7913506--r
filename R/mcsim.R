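#' Monte Carlo simulation of diffuse reflectance from layered skin
#'
#' Photon-packet transport through a stack of plane-parallel turbid layers
#' with the classical hop-drop-spin rule set: exponential free-path
#' sampling against the local total attenuation, a weight drop of
#' mu_a/mu_t per interaction, Henyey-Greenstein angular deflection,
#' Fresnel reflection/refraction at every horizontal boundary (including
#' the tissue-air interface), and Russian roulette termination of light
#' packets. Only the total (spatially integrated) diffuse reflectance and
#' transmittance are tallied.
#'
#' @name mcsim
NULL

#' Define one tissue layer
#'
#' @param thickness Layer thickness, mm (use a large value such as `1e6`
#'   for an effectively semi-infinite final layer).
#' @param mu_a Absorption coefficient, mm^-1.
#' @param mu_s Scattering coefficient, mm^-1.
#' @param g Scattering anisotropy factor, in (-1, 1).
#' @param n Refractive index (>= 1).
#' @return A `tissue_layer` object.
#' @export
tissue_layer <- function(thickness, mu_a, mu_s, g = 0.9, n = 1.4) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L, thickness > 0,
            is.numeric(mu_a), mu_a >= 0, is.numeric(mu_s), mu_s >= 0,
            g > -1, g < 1, n >= 1)
  structure(list(thickness = thickness, mu_a = mu_a, mu_s = mu_s,
                 g = g, n = n), class = "tissue_layer")
}

#' Monte Carlo run configuration
#'
#' @param n_photons Number of photon packets to launch.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical results (the transport code uses its own deterministic
#'   generator, independent of R's RNG).
#' @param weight_threshold Packet weight below which Russian roulette is
#'   played (default 1e-4).
#' @param roulette_survival Survival probability in roulette (default 0.1);
#'   survivors have their weight amplified by its reciprocal so that the
#'   expected weight is conserved.
#' @param ambient_n Refractive index of the medium above (and below) the
#'   tissue stack; default 1.0 (air).
#' @return An `mc_config` object.
#' @export
mc_config <- function(n_photons = 1e5, seed = 1L, weight_threshold = 1e-4,
                      roulette_survival = 0.1, ambient_n = 1.0) {
  stopifnot(n_photons >= 1, weight_threshold > 0,
            roulette_survival > 0, roulette_survival < 1, ambient_n >= 1)
  structure(list(n_photons = as.double(n_photons), seed = as.double(seed),
                 weight_threshold = weight_threshold,
                 roulette_survival = roulette_survival,
                 ambient_n = ambient_n), class = "mc_config")
}

.layers_to_vectors <- function(layers) {
  if (inherits(layers, "tissue_layer")) layers <- list(layers)
  if (length(layers) == 0L) stop("at least one tissue layer is required")
  if (!all(vapply(layers, inherits, logical(1), "tissue_layer"))) {
    stop("layers must be a list of tissue_layer objects")
  }
  list(thickness = vapply(layers, `[[`, numeric(1), "thickness"),
       mu_a = vapply(layers, `[[`, numeric(1), "mu_a"),
       mu_s = vapply(layers, `[[`, numeric(1), "mu_s"),
       g = vapply(layers, `[[`, numeric(1), "g"),
       n = vapply(layers, `[[`, numeric(1), "n"))
}

#' Run a single Monte Carlo simulation
#'
#' A pencil beam enters the top surface at normal incidence. The returned
#' fractions account for every unit of launched weight: specular
#' reflection at entry, diffuse reflection out of the top, diffuse
#' transmission out of the bottom, absorbed weight, and the (net) weight
#' removed by Russian roulette. The five fractions sum to 1 up to floating
#' point accumulation error (compensated summation is used internally).
#'
#' @param layers A list of [tissue_layer()] objects, top first.
#' @param config An [mc_config()].
#' @return An `mc_result` list with fields `r_specular`, `r_diffuse`,
#'   `t_diffuse`, `absorbed`, `lost_roulette`, `n_photons`. Note
#'   `lost_roulette` is a net quantity (roulette survivors are credited
#'   back); it fluctuates around zero and may be slightly negative.
#' @export
mc_simulate <- function(layers, config = mc_config()) {
  lv <- .layers_to_vectors(layers)
  stopifnot(inherits(config, "mc_config"))
  res <- .mcml_run(lv$thickness, lv$mu_a, lv$mu_s, lv$g, lv$n,
                   config$ambient_n, config$n_photons, config$seed,
                   config$weight_threshold, config$roulette_survival)
  structure(res, class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result>", format(x$n_photons, big.mark = ","), "packets\n")
  for (f in c("r_specular", "r_diffuse", "t_diffuse", "absorbed",
              "lost_roulette")) {
    cat(sprintf("  %-14s %.6f\n", f, x[[f]]))
  }
  invisible(x)
}

# deterministic per-wavelength seed derivation (stays inside 2^53 doubles)
.derive_seed <- function(seed, index) {
  (seed * 2654435761 + index * 40503) %% 2^31
}

#' Simulate a diffuse reflectance spectrum
#'
#' Runs one Monte Carlo simulation per grid wavelength. The tissue stack
#' may vary with wavelength through `tissue_builder`, a function
#' `function(lambda)` returning the layer list. Per-wavelength seeds are
#' derived deterministically from `config$seed`.
#'
#' @param tissue_builder Function mapping a wavelength (nm) to a list of
#'   [tissue_layer()] objects.
#' @param grid Wavelength grid (nm); default the 16-point analysis grid.
#' @param config An [mc_config()].
#' @return Data frame with columns `wavelength_nm` and `reflectance`
#'   (total diffuse reflectance, specular excluded).
#' @export
simulate_spectrum <- function(tissue_builder,
                              grid = wavelength_grid("analysis"),
                              config = mc_config()) {
  stopifnot(is.function(tissue_builder))
  assert_uniform_grid(grid)
  rd <- vapply(seq_along(grid), function(i) {
    layers <- tissue_builder(grid[i])
    if (is.null(layers)) {
      stop("tissue_builder returned no layers at ", grid[i], " nm")
    }
    cfg_i <- config
    cfg_i$seed <- .derive_seed(config$seed, i)
    mc_simulate(layers, cfg_i)$r_diffuse
  }, numeric(1))
  data.frame(wavelength_nm = grid, reflectance = rd)
}

#' Default reduced-scattering model for skin
#'
#' The literature scattering curves behind the calibration are not part of
#' the bundled data; the package ships a configurable power-law stand-in
#' mu_s'(lambda) = a * (lambda/500 nm)^(-b) applied to both epidermis and
#' dermis, with mu_s = mu_s'/(1 - g).
#'
#' @param a Reduced scattering at 500 nm, mm^-1 (default 4.6).
#' @param b Scattering power (default 1.4).
#' @param g Anisotropy factor (default 0.9), constant over wavelength.
#' @return A `scattering_model` list with a function `mu_s(lambda)` and
#'   the parameters.
#' @export
scattering_model <- function(a = 4.6, b = 1.4, g = 0.9) {
  stopifnot(a > 0, b >= 0, g > -1, g < 1)
  structure(list(a = a, b = b, g = g,
                 mu_s_prime = function(lambda) a * (lambda / 500)^(-b),
                 mu_s = function(lambda) a * (lambda / 500)^(-b) / (1 - g)),
            class = "scattering_model")
}

#' Two-layer skin model geometry and optics
#'
#' Builds the wavelength-to-layers function used by the forward model: an
#' epidermis (melanin absorption, default 0.06 mm thick) over a dermis
#' (hemoglobin absorption, default 4.94 mm), both with refractive index
#' 1.4 and a shared scattering model.
#'
#' @param c_metHb,c_HbO,c_HbR Dermal blood volume concentrations, vol.%.
#' @param c_m Epidermal melanosome volume fraction, vol.%.
#' @param scattering A [scattering_model()].
#' @param d_epi,d_derm Layer thicknesses, mm.
#' @param n Refractive index of both layers.
#' @return A function `function(lambda)` returning the two-layer list,
#'   suitable for [simulate_spectrum()].
#' @export
skin_tissue <- function(c_metHb, c_HbO, c_HbR, c_m,
                        scattering = scattering_model(),
                        d_epi = 0.06, d_derm = 4.94, n = 1.4) {
  stopifnot(inherits(scattering, "scattering_model"))
  force(c_metHb); force(c_HbO); force(c_HbR); force(c_m)
  function(lambda) {
    mua_epi <- melanin_mu_a(c_m, lambda)$mu_a
    mua_derm <- total_hemoglobin_mu_a(c_metHb, c_HbO, c_HbR, lambda)$mu_a
    mus <- scattering$mu_s(lambda)
    list(tissue_layer(d_epi, mua_epi, mus, scattering$g, n),
         tissue_layer(d_derm, mua_derm, mus, scattering$g, n))
  }
}

#' Null-absorption path-length library
#'
#' Simulates the scattering geometry once per wavelength with zero
#' absorption, recording for every photon packet that escapes through the
#' top surface the geometric path length it travelled in each layer.
#' Diffuse reflectance for arbitrary per-layer absorption coefficients is
#' then obtained by continuous absorption weighting,
#' Rd = (1 - R_spec) * mean(exp(-sum_l mu_a_l * L_l)), an unbiased
#' estimator of the analog simulation that lets one trajectory set serve a
#' whole concentration grid (common random numbers across grid points).
#'
#' @param grid Wavelength grid, nm.
#' @param scattering A [scattering_model()].
#' @param config An [mc_config()]; `weight_threshold`/`roulette_survival`
#'   are not used (no absorption, finite slab).
#' @param d_epi,d_derm,n Geometry as in [skin_tissue()].
#' @return A `pathlength_library` object.
#' @export
mc_pathlength_library <- function(grid = wavelength_grid("reconstruction"),
                                  scattering = scattering_model(),
                                  config = mc_config(),
                                  d_epi = 0.06, d_derm = 4.94, n = 1.4) {
  assert_uniform_grid(grid)
  stopifnot(inherits(scattering, "scattering_model"),
            inherits(config, "mc_config"))
  sims <- lapply(seq_along(grid), function(i) {
    mus <- scattering$mu_s(grid[i])
    .mcml_pathlengths(c(d_epi, d_derm), c(mus, mus),
                      c(scattering$g, scattering$g), c(n, n),
                      config$ambient_n, config$n_photons,
                      .derive_seed(config$seed, i))
  })
  structure(list(grid = grid, sims = sims, scattering = scattering,
                 config = config, d_epi = d_epi, d_derm = d_derm, n = n),
            class = "pathlength_library")
}

#' @export
print.pathlength_library <- function(x, ...) {
  cat("<pathlength_library>", length(x$grid), "wavelengths,",
      format(x$config$n_photons, big.mark = ","), "packets each\n")
  invisible(x)
}

#' Diffuse reflectance spectrum from a path-length library
#'
#' @param lib A [mc_pathlength_library()] object.
#' @param mua_epi,mua_derm Absorption coefficients (mm^-1) of epidermis and
#'   dermis on `lib$grid` (vectors of the grid length, or scalars).
#' @return Numeric vector of total diffuse reflectance on `lib$grid`.
#' @export
reflectance_from_pathlengths <- function(lib, mua_epi, mua_derm) {
  stopifnot(inherits(lib, "pathlength_library"))
  k <- length(lib$grid)
  mua_epi <- rep_len(mua_epi, k)
  mua_derm <- rep_len(mua_derm, k)
  if (any(mua_epi < 0) || any(mua_derm < 0)) stop("mu_a must be non-negative")
  vapply(seq_len(k), function(i) {
    s <- lib$sims[[i]]
    Lm <- s$lengths_top
    w <- exp(-(Lm[, 1L] * mua_epi[i] + Lm[, 2L] * mua_derm[i]))
    (1 - s$r_specular) * sum(w) / s$n_photons
  }, numeric(1))
}
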