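# Receptor-space facial color metrics.
#
# Japanese macaques are trichromats but facial redness is carried by the
# long-wave (LW) vs medium-wave (MW) opponency, so the analysis works on the
# two modeled captures: a photograph's region-mean camera RGB is mapped to
# (LW, MW) through an affine calibration fitted per session against a color
# chart of known reflectances, and the two outcomes are
#   rg_ratio  = (LW - MW) / (LW + MW)   (redness, dimensionless in (-1, 1))
#   luminance = (LW + MW) / 2           (lightness, capture units)

#' Construct a receptor model
#'
#' A receptor model holds the LW and MW spectral sensitivities as per-band
#' weights plus the illuminant, all on a common band grid. Sensitivities are
#' normalized to unit peak. Expected receptor captures of a surface are
#' `sensitivity %*% (illuminant * reflectance)`.
#'
#' @param sensitivities 2 x B non-negative matrix with rownames `LW`, `MW`.
#' @param illuminant Length-B non-negative illuminant weights.
#' @return A `receptor_model` list.
#' @export
receptor_model <- function(sensitivities, illuminant) {
  if (!is.matrix(sensitivities) || nrow(sensitivities) != 2) {
    abort("`sensitivities` must be a 2 x B matrix (rows LW, MW)")
  }
  if (any(sensitivities < 0) || any(illuminant < 0)) {
    abort("sensitivities and illuminant must be non-negative")
  }
  if (ncol(sensitivities) != length(illuminant)) {
    abort("illuminant length must match the number of bands")
  }
  peak <- apply(sensitivities, 1, max)
  if (any(peak == 0)) abort("each receptor needs a positive peak sensitivity")
  out <- list(
    sensitivities = sensitivities / peak,
    illuminant = as.numeric(illuminant),
    n_bands = length(illuminant)
  )
  rownames(out$sensitivities) <- c("LW", "MW")
  class(out) <- "receptor_model"
  out
}

# fixed 3 x 6 synthetic camera sensor matrix (R, G, B rows over 6 bands)
synthetic_camera <- function() {
  matrix(c(
    0.02, 0.03, 0.08, 0.25, 0.85, 1.00,  # R: long-wave biased
    0.05, 0.25, 0.90, 1.00, 0.35, 0.08,  # G: mid-band
    1.00, 0.80, 0.25, 0.08, 0.03, 0.01   # B: short-wave
  ), nrow = 3, byrow = TRUE, dimnames = list(c("R", "G", "B"), NULL))
}

#' Synthetic macaque receptor model (non-biological)
#'
#' A SYNTHETIC stand-in for measured Japanese macaque LW/MW cone
#' sensitivities, which are not shipped with the package: the receptor
#' sensitivities are constructed as fixed linear combinations of the
#' synthetic camera bands, so that receptor captures are an exact linear
#' function of camera RGB and calibration behaves ideally. Use it for
#' testing and simulation only; supply measured sensitivity tables via
#' [receptor_model()] for real analyses.
#'
#' @return A `receptor_model` over 6 spectral bands with a flat illuminant.
#' @export
synthetic_receptor_model <- function() {
  cam <- synthetic_camera()
  w <- matrix(c(0.80, 0.30, 0.02,
                0.15, 0.90, 0.05), nrow = 2, byrow = TRUE)
  receptor_model(w %*% cam, illuminant = rep(1, ncol(cam)))
}

#' Synthetic chart patch reflectances
#'
#' A deterministic 24-patch reflectance table over the synthetic 6-band grid,
#' mimicking the structure of a 24-square color-rendition chart: a 6-step
#' neutral (gray) ramp plus 18 chromatic patches with varying band peaks.
#' All reflectances lie in \[0, 1\].
#'
#' @return A tibble with `patch_id` and band columns `b1`..`b6`.
#' @export
synthetic_chart_reflectance <- function() {
  grays <- outer(seq(0.05, 0.95, length.out = 6), rep(1, 6))
  peaks <- matrix(0.08, nrow = 6, ncol = 6)
  diag(peaks) <- 0.85
  bands <- seq_len(6)
  mixed <- t(vapply(seq_len(12), function(p) {
    0.15 + 0.35 * (1 + sin(p * bands / 2 + p)) / 1
  }, numeric(6)))
  mixed <- pmin(pmax(mixed, 0), 1)
  refl <- rbind(grays, peaks, mixed)
  out <- tibble::as_tibble(refl, .name_repair = ~ paste0("b", seq_len(6)))
  dplyr::bind_cols(tibble::tibble(patch_id = sprintf("P%02d", 1:24)), out)
}

# band columns of a reflectance table, as a matrix
reflectance_matrix <- function(chart_reflectance) {
  bands <- grep("^b[0-9]+$", names(chart_reflectance), value = TRUE)
  as.matrix(chart_reflectance[, bands])
}

#' Expected receptor captures of chart patches
#'
#' Computes the LW/MW captures each chart patch should produce under the
#' receptor model: `sensitivity %*% (illuminant * reflectance)` per patch.
#'
#' @param chart_reflectance Tibble with `patch_id` and band columns (`b1`...).
#' @param model A [receptor_model()].
#' @return A tibble `patch_id`, `LW`, `MW`.
#' @export
expected_captures <- function(chart_reflectance, model) {
  refl <- reflectance_matrix(chart_reflectance)
  if (ncol(refl) != model$n_bands) {
    abort("chart reflectance bands do not match the receptor model")
  }
  if (any(refl < 0 | refl > 1)) abort("reflectances must lie in [0, 1]")
  capt <- refl %*% (model$illuminant * t(model$sensitivities))
  tibble::tibble(patch_id = chart_reflectance$patch_id,
                 LW = capt[, 1], MW = capt[, 2])
}

#' Fit a session calibration mapping camera RGB to receptor captures
#'
#' Ordinary least-squares affine map from measured chart-patch RGB (under one
#' session's exposure) to the patches' expected receptor captures. Because
#' face and chart share the exposure, applying the map standardizes
#' measurements across sessions. Returns the fitted map and the residual RMS
#' for quality control.
#'
#' @param chart_rgb Tibble of measured patch means: `patch_id`, `r`, `g`, `b`.
#' @param captures Expected captures from [expected_captures()], or a tibble
#'   `patch_id`, `LW`, `MW`.
#' @return A `color_calibration` object: `coefficients` (4 x 2: intercept and
#'   RGB slopes for each of LW, MW), `residual_rms`, `n_patches`.
#' @export
fit_calibration <- function(chart_rgb, captures) {
  assert_columns(chart_rgb, c("patch_id", "r", "g", "b"), "chart_rgb")
  assert_columns(captures, c("patch_id", "LW", "MW"), "captures")
  df <- dplyr::inner_join(chart_rgb, captures, by = "patch_id")
  if (nrow(df) < 4) abort("calibration needs at least 4 chart patches")
  x <- cbind(1, df$r, df$g, df$b)
  if (qr(x)$rank < 4) {
    abort("chart patch RGB set is rank-deficient; cannot fit calibration")
  }
  y <- cbind(LW = df$LW, MW = df$MW)
  fit <- stats::lm.fit(x, y)
  coefs <- fit$coefficients
  rownames(coefs) <- c("(Intercept)", "r", "g", "b")
  out <- list(
    coefficients = coefs,
    residual_rms = sqrt(mean(fit$residuals^2)),
    n_patches = nrow(df)
  )
  class(out) <- "color_calibration"
  out
}

#' @export
print.color_calibration <- function(x, ...) {
  cat("<color_calibration>", x$n_patches, "patches, residual RMS",
      format(x$residual_rms, digits = 4), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Convert region-mean RGB to receptor-space color measurements
#'
#' Applies a session calibration to region-mean camera RGB and computes the
#' two facial color outcomes: the red-green opponency ratio
#' `(LW - MW)/(LW + MW)` and the luminance `(LW + MW)/2`. Rows whose mapped
#' captures are non-positive are rejected with an error, since the outcomes
#' are undefined there.
#'
#' @param rgb_tbl Tibble with columns `r`, `g`, `b` (region means on linear
#'   values) plus any identifier columns, which are carried through.
#' @param calibration A [fit_calibration()] result.
#' @return The input tibble with `LW`, `MW`, `rg_ratio`, `luminance` added.
#' @export
measure_face <- function(rgb_tbl, calibration) {
  assert_columns(rgb_tbl, c("r", "g", "b"), "rgb_tbl")
  if (!inherits(calibration, "color_calibration")) {
    abort("`calibration` must come from fit_calibration() (missing session calibration?)")
  }
  x <- cbind(1, rgb_tbl$r, rgb_tbl$g, rgb_tbl$b)
  capt <- x %*% calibration$coefficients
  if (any(capt <= 0)) {
    abort("mapped receptor captures must be positive; check calibration/exposure")
  }
  rgb_tbl |>
    dplyr::mutate(
      LW = capt[, 1],
      MW = capt[, 2],
      rg_ratio = (.data$LW - .data$MW) / (.data$LW + .data$MW),
      luminance = (.data$LW + .data$MW) / 2
    )
}

#' Region-mean RGB of a masked image region
#'
#' Arithmetic mean of the in-mask pixels of a linear-RGB image. Linearization
#' (RAW development, gamma removal) is assumed done upstream.
#'
#' @param image Numeric array H x W x 3 of linear RGB values.
#' @param mask Logical H x W matrix; `TRUE` pixels enter the mean. Build one
#'   from a polygon with [polygon_mask()].
#' @return A tibble with one row: `r`, `g`, `b`, `n_pixels`.
#' @export
extract_region <- function(image, mask) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("`image` must be an H x W x 3 array")
  }
  if (!is.logical(mask) || !all(dim(mask) == dim(image)[1:2])) {
    abort("`mask` must be a logical matrix matching the image dimensions")
  }
  n <- sum(mask)
  if (n == 0) abort("mask is empty")
  tibble::tibble(
    r = mean(image[, , 1][mask]),
    g = mean(image[, , 2][mask]),
    b = mean(image[, , 3][mask]),
    n_pixels = n
  )
}

#' Rasterize a polygon into a pixel mask
#'
#' Even-odd (crossing-number) point-in-polygon test at pixel centers, for
#' building the face-region mask from user-drawn polygon vertices.
#'
#' @param nrow,ncol Image dimensions.
#' @param poly_x,poly_y Polygon vertices in pixel coordinates (column, row).
#' @return Logical `nrow` x `ncol` matrix.
#' @export
polygon_mask <- function(nrow, ncol, poly_x, poly_y) {
  if (length(poly_x) < 3 || length(poly_x) != length(poly_y)) {
    abort("polygon needs at least 3 (x, y) vertices")
  }
  px <- rep(seq_len(ncol), each = nrow)
  py <- rep(seq_len(nrow), times = ncol)
  inside <- rep(FALSE, length(px))
  nv <- length(poly_x)
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((poly_y[i] > py) != (poly_y[j] > py)) &
      (px < (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
         (poly_y[j] - poly_y[i]) + poly_x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = nrow, ncol = ncol)
}

#' Per-photo color outcomes on the modeling scale
#'
#' Joins period labels onto color measurements and adds the outcomes the
#' Gaussian mixed models use: `log_luminance` (natural log; luminance is
#' lognormal-like and strictly positive) and `rg_ratio` untransformed (it can
#' be negative or zero, so a log transform is ill-defined; see the methods
#' vignette).
#'
#' @param measurements Tibble from [measure_face()] with `female_id`, `date`.
#' @param labels Period labels from [label_periods()] (`female_id`, `date`,
#'   `period`), or `NULL` if `measurements` already has a `period` column.
#' @return Tibble with `period`, `log_luminance`, `rg_ratio` per photo.
#' @export
color_outcomes <- function(measurements, labels = NULL) {
  assert_columns(measurements, c("female_id", "date", "luminance", "rg_ratio"),
                 "measurements")
  out <- measurements
  if (!is.null(labels)) {
    assert_columns(labels, c("female_id", "date", "period"), "labels")
    out <- dplyr::left_join(out,
                            dplyr::select(labels, "female_id", "date", "period"),
                            by = c("female_id", "date"))
  } else {
    assert_columns(out, "period", "measurements")
  }
  if (any(out$luminance <= 0)) abort("luminance must be positive to log-transform")
  dplyr::mutate(out, log_luminance = log(.data$luminance))
}
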