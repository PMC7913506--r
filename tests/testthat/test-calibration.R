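# calibration grid, dataset construction, MRA2

test_that("default grid enumerates exactly 1550 states (1650 complete)", {
  st <- enumerate_states(grid_spec())
  expect_equal(nrow(st), 1550)
  expect_equal(nrow(enumerate_states(grid_spec(), complete = TRUE)),
               10 * 5 * 33)
  # 31 states per (c_m, c_hbt) cell
  percell <- table(paste(st$c_m, st$c_hbt))
  expect_true(all(percell == 31))
  # component concentrations are consistent partitions of C_HbT
  expect_equal(st$c_metHb + st$c_HbO + st$c_HbR, st$c_hbt)
  expect_true(all(st$c_metHb >= 0 & st$c_HbO >= 0 & st$c_HbR >= 0))
  expect_equal(st$sto2, 100 * st$c_HbO / st$c_hbt)
  # one value per axis -> a single record
  g1 <- grid_spec(5, 0.6, 50, 0)
  expect_equal(nrow(enumerate_states(g1)), 1)
})

test_that("build_dataset produces physical spectra and MRA1 coefficients", {
  g <- grid_spec(c_m_values = 4, c_hbt_values = 0.6,
                 sto2_values = c(0, 100), methb_fraction_values = 0)
  ds <- build_dataset(g, mc_config(2e3, seed = 2), method = "direct")
  expect_equal(nrow(ds$records), 2)
  expect_equal(ncol(ds$spectra), 16)
  expect_true(all(ds$spectra > 0 & ds$spectra < 1))
  expect_true(all(c("a_metHb", "a_0") %in% names(ds$records)))
  # fixture: path-length route at scale
  ds2 <- fx_dataset()
  expect_equal(nrow(ds2$records), 208)
  expect_true(all(ds2$spectra > 0 & ds2$spectra < 1))
})

test_that("path-length and direct dataset routes agree at a shared grid point", {
  g <- grid_spec(c_m_values = 4, c_hbt_values = 0.6, sto2_values = 50,
                 methb_fraction_values = 0.25)
  dsa <- build_dataset(g, mc_config(1e4, seed = 5), method = "pathlength")
  dsb <- build_dataset(g, mc_config(1e4, seed = 6), method = "direct")
  expect_lt(max(abs(dsa$spectra - dsb$spectra) / dsb$spectra), 0.08)
})

test_that("fit_mra2 recovers an exact linear relation and ignores record order", {
  set.seed(6)
  n <- 60
  a <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("a_metHb", "a_HbO", "a_HbR", "a_m",
                                      "a_0")))
  rec <- as.data.frame(a)
  rec$c_metHb <- 2 * a[, 1] + 0.5 * a[, 5] + 1
  rec$c_HbO <- a[, 2] - a[, 3]
  rec$c_HbR <- 3 * a[, 3]
  rec$c_m <- a[, 4] + 4
  m <- fit_mra2(rec, order = 2)
  pred <- predict_concentrations(m, a)
  expect_equal(pred[, "C_metHb"], rec$c_metHb, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(pred[, "C_m"], rec$c_m, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(m$r_squared > 1 - 1e-12))
  expect_equal(m$z, 21L)
  # permutation invariance
  perm <- sample(n)
  m2 <- fit_mra2(rec[perm, ], order = 2)
  expect_equal(m2$b, m$b, tolerance = 1e-6)
})

test_that("fit_mra2 flags rank deficiency and undersized datasets", {
  set.seed(7)
  a <- matrix(rnorm(100), 20, 5,
              dimnames = list(NULL, c("a_metHb", "a_HbO", "a_HbR", "a_m",
                                      "a_0")))
  rec <- as.data.frame(a)
  rec$c_metHb <- rec$c_HbO <- rec$c_HbR <- rec$c_m <- rnorm(20)
  expect_error(fit_mra2(rec, order = 2), "more than z")
  rec2 <- rec[rep(1:20, 3), ]
  rec2$a_m <- rec2$a_0  # exact collinearity
  expect_error(fit_mra2(rec2, order = 2), "rank-deficient")
})

test_that("quadratic MRA2 explains the calibration dataset (R^2 >= 0.95)", {
  m <- fx_model()
  expect_true(all(m$r_squared >= 0.95))
})

test_that("estimated StO2 is monotone along oxygenation grid lines", {
  ds <- fx_dataset()
  m <- fx_model()
  rec <- ds$records
  est <- predict_concentrations(
    m, as.matrix(rec[, c("a_metHb", "a_HbO", "a_HbR", "a_m", "a_0")]))
  est <- pmin(pmax(est, 0), 100)
  hbt <- rowSums(est[, 1:3])
  sto2 <- ifelse(hbt > 0, 100 * est[, "C_HbO"] / hbt, NA)
  cells <- split(seq_len(nrow(rec)),
                 paste(rec$c_m, rec$c_hbt, rec$methb_frac))
  for (idx in cells) {
    ord <- idx[order(rec$s_func[idx])]
    if (length(ord) > 1) {
      expect_true(all(diff(sto2[ord]) > -1))  # non-decreasing (1 pt slack)
    }
  }
})

test_that("closed-loop leave-one-out recovery meets the artifact gates", {
  cl <- fx_loo()
  expect_true(all(cl$median_rel_error <= 0.15))
  expect_true(all(abs(cl$sto2_error) <= 10, na.rm = TRUE))
})

test_that("dataset CSV and model JSON round-trips preserve content", {
  ds <- fx_dataset()
  f <- withr::local_tempfile(fileext = ".csv")
  write_calibration_dataset(ds, f)
  ds2 <- read_calibration_dataset(f)
  expect_equal(ds2$wavelengths, ds$wavelengths)
  expect_equal(ds2$spectra, ds$spectra, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ds2$records$a_metHb, ds$records$a_metHb, tolerance = 1e-12)
  m <- fx_model()
  fj <- withr::local_tempfile(fileext = ".json")
  save_inverse_model(m, fj)
  m2 <- read_inverse_model(fj)
  expect_equal(m2$b, m$b, tolerance = 1e-12)
  expect_equal(m2$order, m$order)
  a5 <- as.matrix(ds$records[1:3, c("a_metHb", "a_HbO", "a_HbR", "a_m",
                                    "a_0")])
  expect_equal(predict_concentrations(m2, a5), predict_concentrations(m, a5))
})

test_that("camera-consistent reprojection changes coefficients but keeps truth columns", {
  ds <- fx_dataset_complete()
  dsr <- reproject_dataset(ds, fx_wiener())
  expect_true(isTRUE(dsr$camera_consistent))
  expect_equal(dsr$records$c_metHb, ds$records$c_metHb)
  expect_false(isTRUE(all.equal(dsr$records$a_metHb, ds$records$a_metHb)))
  m <- fx_model_cam()
  expect_s3_class(m, "empirical_inverse_model")
})
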