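---
title: "hemospect: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hemospect: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what is modeled, which
parameters matter, what the synthetic data generator does and does not
emulate, and where the design was genuinely open and a choice had to be made.
Every quantitative statement here is one the test suite or the acceptance
script computes; nothing is asserted from memory of external results.

## 1. The estimation problem

Skin color in the visible band is dominated by four absorbers: melanin in
the epidermis and three hemoglobin species in the dermal blood —
oxygenated (HbO), deoxygenated (HbR) and methemoglobin (metHb), the
dysfunctional Fe³⁺ form whose 630 nm absorption band gives
methemoglobinemia its characteristic slate-gray cyanosis. The package
estimates per-pixel volume concentrations of all four, plus total
hemoglobin `C_HbT = C_metHb + C_HbO + C_HbR` (note: *including* the
dyshemoglobin — some literature excludes it) and tissue oxygen saturation
`StO2 = 100 * C_HbO / C_HbT` (reported as missing where `C_HbT = 0`;
0/0 is undefined, not zero), from a single RGB exposure.

The chain has four stages, each linear or polynomial so that whole images
are processed as matrix contractions rather than per-pixel loops:

1. **Wiener spectral reconstruction** (RGB → 29-channel reflectance,
   420–700 nm / 10 nm);
2. **absorbance** `A = log10(1/r)` restricted to the 16-channel analysis
   band (500–650 nm / 10 nm) where the hemoglobin Q-bands and the metHb
   630 nm band live;
3. **MRA1**: ordinary least squares of `A(λ)` on the four extinction
   spectra plus an intercept. The intercept stands in for scattering
   attenuation treated as a pseudochromophore; the slopes conflate
   concentration with mean photon path length, which is why they cannot be
   read as concentrations directly;
4. **MRA2**: empirical polynomial formulae `C_x = b_x · a`, with `a` the
   degree-2 feature vector of the five MRA1 coefficients (constant + 5
   linear + 5 squares + 10 products, z = 21), fitted on Monte
   Carlo-simulated spectra with known ground truth.

The degree-2 choice is the smallest nonlinear extension of the linear
feature set: degree 1 leaves clear curvature in the coefficient-to-
concentration map (visibly lower in-sample R²), while degree 3 triples the
feature count against at most 1550 training records. The order is a
`fit_mra2()` argument.

## 2. The forward model

### 2.1 Chromophore data

Extinction tabulations are bundled as CSV assets on 400–700 nm / 10 nm
(`inst/extdata/chromophores/`), compiled from the standard literature
tabulations of hemoglobin molar extinction; their provenance headers mark
them as approximate interpolations. The features the method depends on are
present and tested: the HbO double peak (542/576 nm) with its local
minimum near 560 nm, the broad single HbR band with elevated red
absorption, and the metHb 630 nm band exceeding HbO there by almost an
order of magnitude. Melanin uses the standard melanosome power law
`mu_a = 1.70e11 * lambda^-3.48 mm^-1` (per unit melanosome volume
fraction). Because the package is self-consistent — calibration and
inversion share one set of tables — absolute tabulation accuracy shifts
only the physical interpretation of the outputs, not any internal result.

Unit conventions (all in `chromophores.R`):

* 100 vol.% blood ≡ 150 g/L hemoglobin; with molar mass 64,500 g/mol this
  fixes the blood molarity at 150/64500 mol/L, so
  `mu_a = ln(10) * eps * (150/64500) * (c/100)` per cm, stored in mm⁻¹.
* Melanin "vol.%" is the melanosome volume fraction of the epidermis. The
  source literature's melanin unit system is not printed anywhere we could
  bundle, so this scale is a package convention: C_m values are comparable
  within this artifact, not across instruments.
* Resampling is linear interpolation; queries outside 400–700 nm are
  errors, never extrapolated.

### 2.2 Photon transport

`mc_simulate()` is a classical photon-packet random walk through
plane-parallel layers: exponential step sampling against `mu_t`, weight
drop `w * mu_a/mu_t` per interaction, Henyey–Greenstein deflection,
unpolarized Fresnel reflection/refraction at every horizontal interface,
Russian roulette below `weight_threshold`. It is written in C++ (Rcpp)
with its own deterministic xoshiro256** generator, so identical seeds give
bit-identical results on any platform, independent of R's RNG state.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| epidermis / dermis thickness | 0.06 / 4.94 mm | the two-layer skin geometry the calibration states |
| refractive index | 1.4 both layers, ambient 1.0 | standard soft-tissue value |
| `mu_s'(λ)` | `4.6 * (λ/500 nm)^-1.4` mm⁻¹, both layers | configurable power-law stand-in; the literature scattering curves behind the original calibration are not printed anywhere bundleable, so absolute concentration scales depend on this choice (see §6) |
| `g` | 0.9, wavelength-independent | typical dermal anisotropy |
| `weight_threshold` / `roulette_survival` | 1e-4 / 0.1 | conventional packet-transport defaults |
| `n_photons` | 1e5 (config), 1e4/λ in tests, 5e6/λ available | 5e6 is the reference-fidelity setting; tests use the reduced scale their criteria prescribe |

One deliberate deviation from convention: roulette survivors have their
weight amplified by `1/p`, which breaks exact per-run energy accounting.
`lost_roulette` is therefore tallied as the *net* removed weight (a kill
adds `w`, a survival adds `w - w/p < 0`), so
`r_specular + r_diffuse + t_diffuse + absorbed + lost_roulette = 1` holds
to 1e-12 for every run (compensated summation on the tallies) while the
estimator stays unbiased. The price: `lost_roulette` fluctuates around
zero and can be slightly negative.

### 2.3 The path-length library

Simulating the calibration grid analog-style is one run per (state,
wavelength): 1550 × 16 runs at full scale. Because every grid state shares
the same scattering geometry at a given wavelength, the package instead
simulates each wavelength once with zero absorption, records the geometric
path length each escaping packet accumulated in each layer, and evaluates
any absorption combination by continuous absorption weighting,
`Rd = (1 - R_spec) * mean(exp(-mu_a_epi * L_epi - mu_a_derm * L_derm))`.
This "white Monte Carlo" rescaling is an unbiased estimator of the analog
walk; the test suite cross-checks it against the direct engine at shared
optics. It also introduces common random numbers across grid states, which
suppresses state-to-state noise in the calibration — a feature for fitting,
but worth knowing when interpreting leave-one-out errors as absolute
accuracy. `build_dataset(method = "direct")` is the analog route.

### 2.4 The calibration grid

Melanin 1–10 vol.% (step 1) × total hemoglobin 0.2–1.0 vol.% (step 0.2) ×
31 oxygenation/metHb states per cell = 1550 spectra. The 31 states are
reconstructed as: metHb fraction `f ∈ {0, 0.25, 0.5}` of C_HbT crossed
with functional saturation `s ∈ {0, 0.1, …, 1}` of the remaining
hemoglobin (`C_metHb = f·HbT`, `C_HbO = s(1-f)·HbT`,
`C_HbR = (1-s)(1-f)·HbT`), minus the two fully oxygenated states with
`f > 0`. The crossing is a package reconstruction — only the total 1550
constrains it — and the trim rule (overt methemoglobinemia with fully
oxygenated functional blood is outside the calibrated world) is the
documented tie-break. `enumerate_states(complete = TRUE)` keeps all 33
states per cell, which makes the grid a complete tensor; the phantom
interpolator requires that.

## 3. Wiener estimation

The camera model `F = UES` ships with a generic default (Gaussian
passbands at 610/540/460 nm, 60 nm FWHM, flat illuminant and sensitivity);
real deployments supply manufacturer curves via
`camera_spectral_model()`/`read_camera_profile()`. Responses are white
balanced against a 99% reflectance diffuser — simulated for phantoms — so
the effective system matrix maps spectra to unit-white responses; dark
current is assumed already subtracted. The training ensemble is, by
default, simulated skin spectra drawn from the calibration library (the
original method used measured spectra; none can be bundled), with a CSV
loader for user ensembles. An optional 3 × 3 noise covariance enters the
inverted core. Reconstructed reflectance is clipped to [0, 1] with the
clipped fraction logged and a warning above 1%, because the next stage
takes a logarithm.

## 4. Camera-consistent calibration (a finding)

The calibration procedure as usually stated fits MRA2 on MRA1 coefficients
of the *raw* simulated spectra. During integration we found this corrupts
the end-to-end pipeline even when reconstruction looks excellent: an RGB
response has three degrees of freedom, so reconstructed spectra — and
their MRA1 coefficient vectors — live on a curved 3-dimensional manifold.
Coefficients of raw 16-channel spectra sit slightly off that manifold, and
a quadratic fitted there extrapolates without control when evaluated on
it; in our synthetic world the C_metHb estimate inverted sign along a
metHb ramp at reconstruction GFC above 0.9999. The remedy is to calibrate
through the same channel used at inference: `reproject_dataset()` pushes
every calibration spectrum through `F` and `W` before MRA1, and
`fit_mra2(rank_action = "minnorm")` handles the rank deficiency this
induces (the quadratic design of on-manifold coefficients has exact linear
dependencies) with a minimum-norm SVD least-squares solution. The
paper-faithful raw route remains the default of `fit_mra2()` and is what
the raw-spectrum closed-loop tests use; the imaging pipeline tests and the
phantom documentation use the camera-consistent model.

## 5. The synthetic world

The phantom generator emulates the *measurement structure* of a
transcutaneous imaging experiment: per-pixel ground-truth concentration
maps, forward spectra by multilinear interpolation of the simulated
library (exact at grid nodes; per-pixel Monte Carlo at image scale is not
desk-feasible), projection through the white-balanced camera matrix,
additive Gaussian sensor noise (default sigma = 0.5% of full scale — a
plausible figure for a machine-vision CCD after white balance; there is no
stated hardware value to adopt) and quantization (default 8 bit). Scenes
require an explicit seed and regenerate bit-identically. The
methemoglobinemia series moves metHb along a double-exponential pulse
(defaults tau_rise 15 min, tau_decay 90 min — chosen to place the
half-maximum rise inside 30 min and recovery on the hours scale, the
qualitative shape of nitrite challenges) with HbO reduced in compensation
so C_HbT stays constant.

What a green test does **not** establish: the generator draws from the same
family of spectra the calibration simulates, so end-to-end successes
demonstrate internal consistency of the pipeline, not accuracy on real
skin. Real tissue adds vasculature texture, depth-structured chromophores,
specular residue, motion, and scattering spectra that differ from the
power-law stand-in — none of which are emulated.

## 6. Numerical choices

* Reflectance floor 1e-4 before the absorbance log (clipped Wiener output
  can be 0); floored pixel counts are reported in map metadata.
* Concentration estimates are clipped to [0, 100] vol.% with `clipped`
  flags and raw values preserved — the polynomial can extrapolate outside
  physics.
* MRA1 is a fixed 5 × 16 projection (normal equations solved once), with a
  collinearity guard on the scaled design's condition number.
* MRA2 standardizes features internally and back-transforms exactly;
  rank-deficient designs are an error unless `rank_action = "minnorm"`.
* GFC label boundaries follow the printed semantics exactly: strict `>`
  at 0.995, `>=` at 0.999 and 0.9999.
* Per-wavelength Monte Carlo seeds are derived deterministically from the
  run seed; all seeds stay below 2³¹.

## 7. Known limitations

* **Identifiability.** Four chromophores plus a scattering offset cannot be
  uniquely determined from three camera channels; the state-to-response
  map is mathematically non-injective. Estimates are reliable along
  constrained trajectories (one dominant varying chromophore, e.g. a
  methemoglobinemia time course at roughly constant C_HbT) and for the
  well-separated quantities (C_m, C_HbT, StO2); fully independent random
  variation of all four cannot be resolved, and the test suite asserts
  ladder monotonicity rather than joint recovery for exactly this reason.
* **Absolute scales.** The scattering model and the melanin unit system are
  documented stand-ins; changing them rescales the empirical formulae.
  Concentrations are comparable within a calibration, and epidermal
  thickness differences shift the melanin/hemoglobin split.
* **No depth resolution**; the model assumes homogeneous layers.
* The per-spectrum Monte Carlo noise floor at desk scale (1e4 packets per
  wavelength) is visible in the closed-loop errors; the 5e6-packet setting
  exists for reference-quality calibration runs.
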