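# camera forward model and Wiener estimation

test_that("system_matrix discretizes the channel integrals", {
  wl <- wavelength_grid("reconstruction")
  k <- length(wl)
  F0 <- system_matrix(default_camera_model())
  expect_equal(dim(F0), c(3L, 29L))
  # delta-like passbands select their bands (times the 10 nm grid step)
  u <- matrix(0, k, 3); u[3, 1] <- 1; u[10, 2] <- 1; u[20, 3] <- 1
  cm <- camera_spectral_model(wl, u, rep(1, k), rep(1, k))
  Fd <- system_matrix(cm)
  r <- runif(k)
  expect_equal(as.vector(Fd %*% r), 10 * r[c(3, 10, 20)])
  # doubling the illuminant doubles every entry
  cm2 <- camera_spectral_model(wl, u, rep(2, k), rep(1, k))
  expect_equal(system_matrix(cm2), 2 * Fd)
})

test_that("autocorrelation averages outer products and is PSD", {
  wl <- wavelength_grid("reconstruction")
  r0 <- runif(29)
  expect_equal(autocorrelation(training_ensemble(matrix(r0, 1), wl)),
               r0 %o% r0)
  expect_equal(autocorrelation(training_ensemble(diag(29), wl)),
               diag(29) / 29)
  set.seed(8)
  sp <- matrix(runif(440 * 29), 440, 29)
  ev <- eigen(autocorrelation(training_ensemble(sp, wl)),
              symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-12))
  expect_error(training_ensemble(sp[0, , drop = FALSE], wl), "at least one")
})

test_that("wiener_matrix reduces to the identity in the square invertible case", {
  set.seed(1)
  a <- crossprod(matrix(rnorm(9), 3)) + diag(3)  # SPD 3x3
  W <- wiener_matrix(a, diag(3))
  expect_equal(W, diag(3), tolerance = 1e-10)
  expect_error(wiener_matrix(a, matrix(1, 2, 3)), "3 rows")
  expect_error(wiener_matrix(matrix(rnorm(9), 3), diag(3)), "symmetric")
})

test_that("Wiener matrix minimizes the ensemble mean squared error", {
  set.seed(2)
  wl <- wavelength_grid("reconstruction")
  F0 <- system_matrix(default_camera_model())
  sp <- matrix(runif(120 * 29), 120, 29)
  ens <- training_ensemble(sp, wl)
  W <- wiener_matrix(autocorrelation(ens), F0)
  V <- F0 %*% t(sp)
  err <- function(W_) mean((t(sp) - W_ %*% V)^2)
  e0 <- err(W)
  # oracle: normal-equations regression of spectra on responses
  W_ols <- t(sp) %*% t(V) %*% solve(V %*% t(V))
  expect_lt(abs(e0 - err(W_ols)), 1e-9)
  for (i in 1:20) {
    expect_gte(err(W + matrix(rnorm(29 * 3, sd = 1e-3), 29, 3)), e0)
  }
})

test_that("rank-deficient ensembles are handled by pseudoinverse", {
  wl <- wavelength_grid("reconstruction")
  F0 <- system_matrix(default_camera_model())
  r0 <- runif(29, 0.1, 0.9)
  sp <- outer(seq(0.5, 1, length.out = 10), r0)  # rank-1 ensemble
  W <- wiener_matrix(autocorrelation(training_ensemble(sp, wl)), F0)
  expect_equal(drop(W %*% (F0 %*% r0)), r0, tolerance = 1e-8)
})

test_that("reconstruct is shape-preserving, linear pre-clip, and exact on low-rank ensembles", {
  set.seed(3)
  wl <- wavelength_grid("reconstruction")
  # rank-3 ensemble: any member is reconstructed exactly
  basis <- matrix(runif(3 * 29, 0.2, 0.8), 3, 29)
  mix <- matrix(runif(60 * 3), 60, 3); mix <- mix / rowSums(mix)
  sp <- mix %*% basis
  wm <- wiener_train(training_ensemble(sp, wl), white_balance = FALSE)
  r17 <- sp[17, ]
  expect_equal(reconstruct(drop(wm$F %*% r17), wm), r17, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(reconstruct(c(0, 0, 0), wm), rep(0, 29), ignore_attr = TRUE)
  v1 <- runif(3); v2 <- runif(3)
  lin <- reconstruct(2 * v1 + 3 * v2, wm, clip = FALSE)
  expect_equal(lin, 2 * reconstruct(v1, wm, clip = FALSE) +
                    3 * reconstruct(v2, wm, clip = FALSE),
               ignore_attr = TRUE)
  v_img <- wm$F %*% t(sp[sample(60, 48, replace = TRUE), ])
  img <- array(t(v_img), c(8, 6, 3))
  stack <- reconstruct(img, wm)
  expect_equal(dim(stack), c(8, 6, 29))
  expect_error(reconstruct(array(0, c(4, 4, 2)), wm), "3 channels")
  expect_error(reconstruct(c(1, 2), wm), "3 elements")
})

test_that("white balance normalizes the response to the 99% diffuser", {
  ds <- fx_dataset_complete()
  wm <- wiener_train(training_ensemble(ds$spectra, ds$wavelengths))
  v_white <- drop(wm$F %*% rep(0.99, 29))
  expect_equal(v_white, c(R = 1, G = 1, B = 1))
})

test_that("camera profile and ensemble CSV round-trips work", {
  wl <- wavelength_grid("reconstruction")
  cm <- default_camera_model()
  prof <- data.frame(wavelength_nm = wl, u1 = cm$u[, 1], u2 = cm$u[, 2],
                     u3 = cm$u[, 3], E = cm$E, S = cm$S)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(prof, f, row.names = FALSE)
  cm2 <- read_camera_profile(f)
  expect_equal(system_matrix(cm2), system_matrix(cm))
  set.seed(4)
  sp <- matrix(runif(5 * 29), 5, 29)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(cbind(data.frame(wavelength_nm = wl), t(sp)), f2,
            row.names = FALSE)
  ens <- read_ensemble(f2)
  expect_equal(ens$spectra, sp, ignore_attr = TRUE)
})

test_that("end-to-end spectral fidelity: median GFC of reconstructed phantom spectra is high", {
  set.seed(5)
  interp <- fx_interp()
  wm <- fx_wiener()
  n <- 120
  hbt <- runif(n, 0.2, 1.0); f <- runif(n, 0, 0.5); s <- runif(n, 0, 1)
  sp <- interpolate_spectra(interp, f * hbt, s * (1 - f) * hbt,
                            (1 - s) * (1 - f) * hbt, runif(n, 1, 10))
  rec <- reconstruct(wm$F %*% t(sp), wm)
  gfcs <- vapply(seq_len(n), function(i) gfc(sp[i, ], rec[, i])$gfc,
                 numeric(1))
  expect_gte(median(gfcs), 0.995)
})
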