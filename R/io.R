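#' Plain-text input/output helpers
#'
#' Images are exchanged as plain (ASCII, "P3") PPM, a text format every
#' image tool can read; spectra and maps as CSV. Camera responses in
#' memory are doubles in [0, 1]; PPM files carry them at the stated bit
#' depth.
#'
#' @name io
NULL

#' Write an RGB array as plain PPM (P3)
#'
#' @param rgb H x W x 3 array with values in [0, 1].
#' @param path Output file.
#' @param maxval Maximum sample value (255 for 8-bit, 65535 for 16-bit).
#' @export
write_rgb_ppm <- function(rgb, path, maxval = 255L) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3] == 3L,
            maxval %in% c(255L, 65535L))
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  px <- round(pmin(pmax(rgb, 0), 1) * maxval)
  # interleave channels pixel by pixel, row-major
  inter <- aperm(px, c(3, 2, 1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), as.character(maxval)), con)
  writeLines(paste(as.integer(inter), collapse = " "), con)
  invisible(path)
}

#' Read a plain PPM (P3) image
#'
#' @param path PPM file.
#' @return H x W x 3 array with values scaled to [0, 1].
#' @export
read_rgb_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P3") stop("only plain (P3) PPM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != 3 * w * h) stop("truncated PPM payload")
  inter <- array(vals, c(3, w, h))
  aperm(inter, c(3, 2, 1)) / maxval
}

#' Write a reflectance spectrum as CSV
#'
#' @param wavelengths Wavelengths, nm.
#' @param reflectance Reflectance values.
#' @param path Output file.
#' @export
write_spectrum_csv <- function(wavelengths, reflectance, path) {
  write.csv(data.frame(wavelength_nm = wavelengths,
                       reflectance = reflectance),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a reflectance spectrum from CSV
#'
#' Expects columns `wavelength_nm` and `reflectance`.
#'
#' @param path CSV file.
#' @return Data frame with those two columns.
#' @export
read_spectrum_csv <- function(path) {
  tab <- read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "reflectance") %in% names(tab))) {
    stop("spectrum CSV needs columns wavelength_nm, reflectance")
  }
  tab[, c("wavelength_nm", "reflectance")]
}

#' Write chromophore maps to a directory
#'
#' One CSV matrix per quantity plus a JSON metadata sidecar (units,
#' clipping counts, dimensions).
#'
#' @param maps A `chromophore_maps` object from [process_image()].
#' @param dir Output directory (created if needed).
#' @export
write_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "chromophore_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qty <- c("C_metHb", "C_HbO", "C_HbR", "C_m", "C_HbT", "StO2")
  for (q in qty) {
    write.table(maps[[q]], file.path(dir, paste0(q, ".csv")), sep = ",",
                row.names = FALSE, col.names = FALSE)
  }
  meta <- list(format = "hemospect_maps_v1",
               units = list(C_metHb = "vol.%", C_HbO = "vol.%",
                            C_HbR = "vol.%", C_m = "vol.%",
                            C_HbT = "vol.%", StO2 = "%"),
               dim = maps$meta$dim, clipped = as.list(maps$meta$clipped),
               reflectance_clipped_fraction = maps$meta$reflectance_clipped,
               absorbance_floored = maps$meta$absorbance_floored)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Save / load a Wiener model as JSON
#'
#' @param model A `wiener_model`.
#' @param path JSON file path.
#' @export
save_wiener_model <- function(model, path) {
  stopifnot(inherits(model, "wiener_model"))
  obj <- list(format = "hemospect_wiener_model_v1",
              wavelengths = model$wavelengths,
              F = apply(model$F, 1, identity, simplify = FALSE),
              W = apply(model$W, 1, identity, simplify = FALSE),
              white_gain = model$white_gain,
              white_balance = model$white_balance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_wiener_model
#' @export
read_wiener_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hemospect_wiener_model_v1")) {
    stop("not a hemospect Wiener model file")
  }
  F_ <- do.call(rbind, obj$F)
  rownames(F_) <- c("R", "G", "B")
  structure(list(F = F_, W = do.call(rbind, obj$W),
                 wavelengths = obj$wavelengths,
                 white_gain = obj$white_gain,
                 white_balance = obj$white_balance),
            class = "wiener_model")
}

#' Write a phantom series bundle
#'
#' Directory layout: `frame_0001.ppm` ..., `truth.csv`, `scene.yaml`.
#'
#' @param series A `phantom_series` from [methemoglobinemia_series()].
#' @param dir Output directory.
#' @param maxval PPM sample depth.
#' @export
write_phantom_bundle <- function(series, dir, maxval = 255L) {
  stopifnot(inherits(series, "phantom_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(series$frames)) {
    write_rgb_ppm(series$frames[[k]]$rgb,
                  file.path(dir, sprintf("frame_%04d.ppm", k)), maxval)
  }
  write.csv(series$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  sc <- series$frames[[1]]$scene
  yaml::write_yaml(list(dim = sc$dim, noise_sd = sc$noise_sd,
                        bit_depth = sc$bit_depth, seed = sc$seed,
                        peak_time_min = series$peak_time),
                   file.path(dir, "scene.yaml"))
  invisible(dir)
}
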