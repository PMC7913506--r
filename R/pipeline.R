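#' End-to-end image processing pipeline
#'
#' An RGB frame is turned into chromophore maps in four linear-algebra
#' steps applied to the whole pixel block at once: Wiener reconstruction
#' (29 x 3 matrix), absorbance on the 16-channel analysis band, the fixed
#' MRA1 projection (5 x 16), and the empirical inverse model (4 x z on
#' polynomial features). Per-pixel loops are avoided entirely.
#'
#' @name pipeline
NULL

#' Process one RGB image into chromophore maps
#'
#' @param rgb H x W x 3 array of white-balance-normalized camera
#'   responses.
#' @param wiener A `wiener_model` from [wiener_train()].
#' @param inverse_model An `empirical_inverse_model` from [fit_mra2()].
#' @return A `chromophore_maps` object: list of H x W matrices `C_metHb`,
#'   `C_HbO`, `C_HbR`, `C_m`, `C_HbT` (vol.%) and `StO2` (%, NA where
#'   C_HbT = 0), plus `meta` (clipping counts and dimensions). Component
#'   estimates are clipped to [0, 100] vol.%; the per-map count of
#'   clipped pixels is reported in `meta$clipped`.
#' @export
process_image <- function(rgb, wiener, inverse_model) {
  stopifnot(inherits(wiener, "wiener_model"),
            inherits(inverse_model, "empirical_inverse_model"))
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L)) {
    stop("rgb must be an H x W x 3 array")
  }
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  v <- t(matrix(rgb, h * w, 3L))                    # 3 x P
  r <- reconstruct(v, wiener)                       # 29 x P, clipped
  A <- absorbance(r[analysis_indices(), , drop = FALSE])  # 16 x P
  a5 <- mra1(A)                                     # 5 x P
  conc <- predict_concentrations(inverse_model, t(a5))    # P x 4
  clipped <- colSums(conc < 0 | conc > 100)
  conc <- pmin(pmax(conc, 0), 100)
  hbt <- rowSums(conc[, c("C_metHb", "C_HbO", "C_HbR"), drop = FALSE])
  sto2 <- ifelse(hbt > 0, 100 * conc[, "C_HbO"] / hbt, NA_real_)

  as_map <- function(x) matrix(x, h, w)
  structure(list(C_metHb = as_map(conc[, "C_metHb"]),
                 C_HbO = as_map(conc[, "C_HbO"]),
                 C_HbR = as_map(conc[, "C_HbR"]),
                 C_m = as_map(conc[, "C_m"]),
                 C_HbT = as_map(hbt),
                 StO2 = as_map(sto2),
                 meta = list(dim = c(h, w), clipped = clipped,
                             reflectance_clipped =
                               attr(r, "clipped_fraction"),
                             absorbance_floored = attr(A, "floored"))),
            class = "chromophore_maps")
}

#' @export
print.chromophore_maps <- function(x, ...) {
  cat("<chromophore_maps>", x$meta$dim[1], "x", x$meta$dim[2], "pixels\n")
  for (q in c("C_metHb", "C_HbO", "C_HbR", "C_m", "C_HbT", "StO2")) {
    cat(sprintf("  %-8s mean %.3f sd %.3f\n", q,
                mean(x[[q]], na.rm = TRUE), stats::sd(x[[q]], na.rm = TRUE)))
  }
  invisible(x)
}

#' Rectangular region of interest
#'
#' @param x0,y0 Top-left pixel (1-based column, row).
#' @param width,height Extent in pixels (default 300 x 300).
#' @return An `roi_spec` object.
#' @export
roi_spec <- function(x0 = 1L, y0 = 1L, width = 300L, height = 300L) {
  stopifnot(x0 >= 1, y0 >= 1, width >= 1, height >= 1)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_spec")
}

#' Mean and standard deviation over a region of interest
#'
#' Missing-value pixels (e.g. StO2 where C_HbT = 0) are excluded and
#' counted.
#'
#' @param map Numeric matrix (one chromophore map).
#' @param roi An [roi_spec()]; must lie inside the map.
#' @return List `mean`, `sd`, `n`, `n_missing`.
#' @export
roi_stats <- function(map, roi = roi_spec()) {
  stopifnot(is.matrix(map), inherits(roi, "roi_spec"))
  if (roi$y0 + roi$height - 1L > nrow(map) ||
      roi$x0 + roi$width - 1L > ncol(map)) {
    stop("ROI extends outside the image (", nrow(map), " x ", ncol(map), ")")
  }
  vals <- map[roi$y0:(roi$y0 + roi$height - 1L),
              roi$x0:(roi$x0 + roi$width - 1L)]
  miss <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  list(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n = length(vals), n_missing = miss)
}

#' Control-normalized signal change
#'
#' Delta M = (M - M_c) / M_c against the designated control sample
#' (e.g. the pre-challenge frame of a time series). Where M_c = 0 the
#' change is undefined and NA is returned.
#'
#' @param m Numeric vector of per-frame signal values.
#' @param control Index of the control frame (default 1).
#' @return Numeric vector of the same length.
#' @export
delta_series <- function(m, control = 1L) {
  stopifnot(is.numeric(m), length(m) >= 1L,
            control >= 1L, control <= length(m))
  mc <- m[control]
  if (!is.finite(mc) || mc == 0) return(rep(NA_real_, length(m)))
  (m - mc) / mc
}

#' Goodness-of-fit coefficient between two spectra
#'
#' Normalized absolute inner product (cosine similarity):
#' GFC = |sum r_mes r_est| / (||r_mes|| ||r_est||), equal to 1 exactly
#' when the spectra are proportional (Cauchy-Schwarz equality). Spectral
#' quality labels: "colorimetrically accurate" requires GFC > 0.995,
#' "good" GFC >= 0.999, "excellent" GFC >= 0.9999; anything else is
#' "below".
#'
#' @param r_mes,r_est Equal-length spectra; neither may be all zero.
#' @return A `gfc_report`: list `gfc`, `label`.
#' @export
gfc <- function(r_mes, r_est) {
  if (length(r_mes) != length(r_est)) stop("spectra must have equal length")
  n1 <- sqrt(sum(r_mes^2)); n2 <- sqrt(sum(r_est^2))
  if (n1 == 0 || n2 == 0) stop("zero-norm spectrum")
  g <- abs(sum(r_mes * r_est)) / (n1 * n2)
  g <- min(g, 1)
  label <- if (g >= 0.9999) "excellent"
           else if (g >= 0.999) "good"
           else if (g > 0.995) "colorimetrically accurate"
           else "below"
  structure(list(gfc = g, label = label), class = "gfc_report")
}

#' @export
print.gfc_report <- function(x, ...) {
  cat(sprintf("<gfc_report> GFC = %.6f (%s)\n", x$gfc, x$label))
  invisible(x)
}
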