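# synthetic phantom generation and the forward interpolator

test_that("forward interpolation is exact at grid nodes and refuses off-hull states", {
  ds <- fx_dataset_complete()
  interp <- fx_interp()
  set.seed(16)
  rows <- sample(nrow(ds$records), 8)
  rec <- ds$records[rows, ]
  sp <- interpolate_spectra(interp, rec$c_metHb, rec$c_HbO, rec$c_HbR,
                            rec$c_m)
  expect_equal(sp, ds$spectra[rows, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # midpoints along one axis are the average of the two node spectra
  mid_cm <- (1 + 4) / 2
  sp_mid <- interpolate_spectra(interp, 0.15, 0.225, 0.225, mid_cm)
  a <- interpolate_spectra(interp, 0.15, 0.225, 0.225, 1)
  b <- interpolate_spectra(interp, 0.15, 0.225, 0.225, 4)
  expect_equal(sp_mid, (a + b) / 2, tolerance = 1e-12)
  expect_error(interpolate_spectra(interp, 0, 0.05, 0.05, 12), "c_m")
  expect_error(interpolate_spectra(interp, 0.7, 0.2, 0.1, 4), "methb_frac")
  expect_error(forward_interpolator(fx_dataset()), "complete")
})

test_that("phantom scenes require a seed and regenerate bit-identically", {
  expect_error(phantom_scene(0.1, 0.3, 0.2, 4), "seed")
  sc <- phantom_scene(0.1, 0.3, 0.2, 4, dim = c(8, 8), seed = 1)
  fr1 <- render_scene(sc, fx_interp(), fx_wiener())
  fr2 <- render_scene(sc, fx_interp(), fx_wiener())
  expect_identical(fr1$rgb, fr2$rgb)
  sc2 <- sc; sc2$seed <- 2L
  expect_false(identical(render_scene(sc2, fx_interp(), fx_wiener())$rgb,
                         fr1$rgb))
})

test_that("zero-noise uniform scenes render constant pixels", {
  sc <- phantom_scene(0.1, 0.3, 0.2, 4, dim = c(6, 9), seed = 3,
                      noise_sd = 0, bit_depth = 16)
  fr <- render_scene(sc, fx_interp(), fx_wiener())
  for (ch in 1:3) {
    expect_equal(max(fr$rgb[, , ch]) - min(fr$rgb[, , ch]), 0)
  }
  expect_equal(dim(fr$spectra), c(6L, 9L, 29L))
  expect_equal(fr$truth$C_HbT, matrix(0.6, 6, 9))
  expect_equal(fr$truth$StO2, matrix(50, 6, 9))
})

test_that("pulse peak time matches numerical maximization", {
  for (taus in list(c(10, 60), c(15, 90), c(5, 200))) {
    tpk <- pulse_peak_time(taus[1], taus[2])
    h <- function(t) exp(-t / taus[2]) - exp(-t / taus[1])
    opt <- optimize(h, c(0, 10 * taus[2]), maximum = TRUE)$maximum
    expect_equal(tpk, opt, tolerance = 1e-4)
  }
  expect_error(pulse_peak_time(90, 15))
})

test_that("methemoglobinemia series has the stated truth structure", {
  base <- phantom_scene(0.02, 0.40, 0.18, 4, dim = c(6, 6), seed = 4)
  ser1 <- methemoglobinemia_series(base, 0.25, 15, 90, n_frames = 1,
                                   dt = 10, interp = fx_interp(),
                                   wiener = fx_wiener())
  expect_equal(ser1$truth$delta_c_metHb, 0)  # baseline only
  ser <- methemoglobinemia_series(base, 0.25, 15, 90, n_frames = 40, dt = 5,
                                  interp = fx_interp(),
                                  wiener = fx_wiener())
  # truth peaks at the frame nearest the analytic maximum
  expect_equal(which.max(ser$truth$delta_c_metHb),
               which.min(abs(ser$truth$time_min - ser$peak_time)))
  # total hemoglobin is held constant along the series
  hbt <- ser$truth$c_metHb + ser$truth$c_HbO + ser$truth$c_HbR
  expect_equal(hbt, rep(hbt[1], 40), tolerance = 1e-12)
  expect_error(methemoglobinemia_series(base, 0.9, 15, 90, 4, 10,
                                        fx_interp(), fx_wiener()),
               "exceeds")
})

test_that("pipeline estimates respond monotonically along single-chromophore ladders", {
  interp <- fx_interp()
  wm <- fx_wiener()
  m <- fx_model_cam()
  est_means <- function(scenes) {
    t(vapply(scenes, function(s) {
      mp <- process_image(render_scene(s, interp, wm)$rgb, wm, m)
      c(met = mean(mp$C_metHb), hbo = mean(mp$C_HbO),
        hbr = mean(mp$C_HbR), cm = mean(mp$C_m), hbt = mean(mp$C_HbT))
    }, numeric(5)))
  }
  k <- 8
  # melanin ladder
  cms <- seq(1.5, 9.5, length.out = k)
  sc_cm <- lapply(seq_len(k), function(i) {
    phantom_scene(0.05, 0.35, 0.2, cms[i], dim = c(8, 8), seed = 20 + i)
  })
  expect_gte(cor(est_means(sc_cm)[, "cm"], cms, method = "spearman"), 0.9)
  # total hemoglobin ladder
  hbts <- seq(0.25, 0.95, length.out = k)
  sc_hbt <- lapply(seq_len(k), function(i) {
    phantom_scene(0.1 * hbts[i], 0.5 * hbts[i], 0.4 * hbts[i], 4,
                  dim = c(8, 8), seed = 40 + i)
  })
  expect_gte(cor(est_means(sc_hbt)[, "hbt"], hbts, method = "spearman"), 0.9)
  # metHb ladder at constant HbT (the methemoglobinemia trajectory)
  mets <- seq(0.02, 0.28, length.out = k)
  sc_met <- lapply(seq_len(k), function(i) {
    phantom_scene(mets[i], 0.42 - mets[i], 0.18, 4, dim = c(8, 8),
                  seed = 60 + i)
  })
  expect_gte(cor(est_means(sc_met)[, "met"], mets, method = "spearman"), 0.9)
  # oxygenation ladder at constant HbT
  ss <- seq(0.05, 0.95, length.out = k)
  sc_s <- lapply(seq_len(k), function(i) {
    phantom_scene(0.05, ss[i] * 0.55, (1 - ss[i]) * 0.55, 4, dim = c(8, 8),
                  seed = 80 + i)
  })
  em <- est_means(sc_s)
  expect_gte(cor(em[, "hbo"], ss, method = "spearman"), 0.9)
  expect_lte(cor(em[, "hbr"], ss, method = "spearman"), -0.9)
})

test_that("PPM round-trip and phantom bundle outputs are written", {
  sc <- phantom_scene(0.05, 0.4, 0.15, 4, dim = c(5, 7), seed = 9)
  fr <- render_scene(sc, fx_interp(), fx_wiener())
  f <- withr::local_tempfile(fileext = ".ppm")
  write_rgb_ppm(fr$rgb, f, maxval = 255L)
  back <- read_rgb_ppm(f)
  expect_equal(back, fr$rgb, tolerance = 1 / 255)
  # rendered frames are already 8-bit quantized, so the round trip is exact
  expect_equal(back, fr$rgb, tolerance = 1e-12)
  base <- phantom_scene(0.02, 0.40, 0.18, 4, dim = c(5, 5), seed = 10)
  ser <- methemoglobinemia_series(base, 0.2, 15, 90, n_frames = 3, dt = 30,
                                  interp = fx_interp(),
                                  wiener = fx_wiener())
  d <- withr::local_tempdir()
  write_phantom_bundle(ser, d)
  expect_true(all(file.exists(file.path(d, c("frame_0001.ppm",
                                             "frame_0003.ppm", "truth.csv",
                                             "scene.yaml")))))
  tr <- read.csv(file.path(d, "truth.csv"))
  expect_equal(tr$delta_c_metHb, ser$truth$delta_c_metHb)
})
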