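test_that("a noise-free affine map is recovered exactly", {
  set.seed(1)
  rgb <- tibble::tibble(patch_id = sprintf("P%02d", 1:24),
                        r = runif(24), g = runif(24), b = runif(24))
  a <- matrix(c(0.9, 0.2, 0.05, 0.1, 0.8, 0.1), nrow = 3)
  offset <- c(0.01, 0.02)
  capt <- as.matrix(rgb[, c("r", "g", "b")]) %*% a
  capt <- sweep(capt, 2, offset, "+")
  captures <- tibble::tibble(patch_id = rgb$patch_id,
                             LW = capt[, 1], MW = capt[, 2])
  cal <- fit_calibration(rgb, captures)
  expect_equal(cal$residual_rms, 0, tolerance = 1e-10)
  expect_equal(unname(cal$coefficients["(Intercept)", ]), offset,
               tolerance = 1e-8)
  expect_equal(unname(cal$coefficients[c("r", "g", "b"), ]), unname(a),
               tolerance = 1e-8)
  # and mapping the patches back reproduces the captures
  m <- measure_face(rgb, cal)
  expect_equal(m$LW, captures$LW, tolerance = 1e-8)
})

test_that("identical LW/MW sensitivities give LW = MW on every patch", {
  cam <- matrix(runif(18, 0.1, 1), nrow = 3)
  model <- receptor_model(rbind(cam[1, ], cam[1, ]), rep(1, 6))
  capt <- expected_captures(synthetic_chart_reflectance(), model)
  expect_equal(capt$LW, capt$MW)
})

test_that("calibration is recovered within 5% under 1% measurement noise", {
  set.seed(42)
  a <- matrix(c(0.9, 0.2, 0.05, 0.1, 0.8, 0.1), nrow = 3)
  ests <- replicate(100, {
    rgb0 <- matrix(runif(72, 0.2, 1), ncol = 3)
    capt <- rgb0 %*% a
    noisy <- rgb0 * (1 + matrix(rnorm(72, 0, 0.01), ncol = 3))
    cal <- fit_calibration(
      tibble::tibble(patch_id = sprintf("P%02d", 1:24),
                     r = noisy[, 1], g = noisy[, 2], b = noisy[, 3]),
      tibble::tibble(patch_id = sprintf("P%02d", 1:24),
                     LW = capt[, 1], MW = capt[, 2]))
    cal$coefficients[c("r", "g", "b"), ]
  })
  mean_est <- apply(ests, c(1, 2), mean)
  expect_true(all(abs(mean_est - a) / abs(a) < 0.05))
})

test_that("calibration errors on degenerate patch sets", {
  rgb <- tibble::tibble(patch_id = sprintf("P%02d", 1:6),
                        r = 0.5, g = 0.5, b = 0.5)
  capt <- tibble::tibble(patch_id = rgb$patch_id, LW = 0.4, MW = 0.3)
  expect_error(fit_calibration(rgb, capt), "rank-deficient")
  expect_error(fit_calibration(rgb[1:3, ], capt[1:3, ]), "at least 4")
})

test_that("color outcomes follow the opponency formulas", {
  cal <- fit_calibration(
    tibble::tibble(patch_id = as.character(1:8),
                   r = runif(8), g = runif(8), b = runif(8)),
    tibble::tibble(patch_id = as.character(1:8),
                   LW = runif(8, 0.2, 1), MW = runif(8, 0.2, 1)))
  # direct-formula checks bypassing the map: equal captures, then 0.6/0.4
  id_cal <- structure(list(
    coefficients = matrix(c(0, 1, 0, 0, 0, 0, 1, 0), ncol = 2,
                          dimnames = list(c("(Intercept)", "r", "g", "b"),
                                          c("LW", "MW"))),
    residual_rms = 0, n_patches = 4L), class = "color_calibration")
  m <- measure_face(tibble::tibble(r = c(0.5, 0.6), g = c(0.5, 0.4),
                                   b = 0), id_cal)
  expect_equal(m$rg_ratio, c(0, 0.2))
  expect_equal(m$luminance, c(0.5, 0.5))
  # swapping channels negates the ratio, leaves luminance
  m_swap <- measure_face(tibble::tibble(r = c(0.5, 0.4), g = c(0.5, 0.6),
                                        b = 0), id_cal)
  expect_equal(m_swap$rg_ratio, -m$rg_ratio)
  expect_equal(m_swap$luminance, m$luminance)
  # non-positive mapped captures are rejected
  expect_error(measure_face(tibble::tibble(r = 0, g = 0.5, b = 0), id_cal),
               "positive")
})

test_that("rg_ratio stays in (-1, 1) and is zero iff LW equals MW", {
  set.seed(5)
  lw <- runif(1000, 1e-6, 10)
  mw <- runif(1000, 1e-6, 10)
  rg <- (lw - mw) / (lw + mw)
  expect_true(all(rg > -1 & rg < 1))
  expect_equal(rg == 0, lw == mw)
})

test_that("rescaling all patch RGB rescales the map but not the captures", {
  set.seed(9)
  rgb <- tibble::tibble(patch_id = as.character(1:24),
                        r = runif(24), g = runif(24), b = runif(24))
  capt <- tibble::tibble(patch_id = rgb$patch_id,
                         LW = runif(24, 0.2, 1), MW = runif(24, 0.2, 1))
  cal1 <- fit_calibration(rgb, capt)
  cc <- 3.7
  rgb2 <- dplyr::mutate(rgb, r = r * cc, g = g * cc, b = b * cc)
  cal2 <- fit_calibration(rgb2, capt)
  expect_equal(cal2$coefficients[c("r", "g", "b"), ],
               cal1$coefficients[c("r", "g", "b"), ] / cc, tolerance = 1e-8)
  m1 <- measure_face(rgb, cal1)
  m2 <- measure_face(rgb2, cal2)
  expect_equal(m1$LW, m2$LW, tolerance = 1e-8)
  expect_equal(m1$rg_ratio, m2$rg_ratio, tolerance = 1e-8)
})

test_that("region extraction equals the naive per-pixel oracle", {
  set.seed(3)
  img <- array(runif(20 * 15 * 3), dim = c(20, 15, 3))
  # uniform image: mean is the value
  uni <- array(0.42, dim = c(4, 4, 3))
  m <- extract_region(uni, matrix(TRUE, 4, 4))
  expect_equal(c(m$r, m$g, m$b), rep(0.42, 3))
  # half a / half b
  half <- array(rep(c(0.2, 0.8), each = 8), dim = c(4, 4, 3))
  m <- extract_region(half, matrix(TRUE, 4, 4))
  expect_equal(m$r, 0.5)
  # random mask vs brute-force loop
  mask <- matrix(runif(20 * 15) < 0.4, 20, 15)
  m <- extract_region(img, mask)
  expect_equal(c(m$r, m$g, m$b), oracle_region_mean(img, mask))
  expect_error(extract_region(img, matrix(FALSE, 20, 15)), "empty")
})

test_that("polygon masks select the polygon interior", {
  # a centered square in a 10x10 image
  mask <- polygon_mask(10, 10, poly_x = c(3, 8, 8, 3), poly_y = c(3, 3, 8, 8))
  expect_true(mask[5, 5])
  expect_false(mask[1, 1])
  expect_false(mask[10, 10])
  expect_error(polygon_mask(5, 5, c(1, 2), c(1, 2)), "at least 3")
})

test_that("color outcomes log-transform luminance and keep rg_ratio linear", {
  m <- tibble::tibble(female_id = "F01", date = as.Date("2014-01-05"),
                      LW = 1.2, MW = 0.8,
                      rg_ratio = 0.2, luminance = 1.0, period = "month1")
  out <- color_outcomes(m)
  expect_equal(out$log_luminance, 0)
  expect_equal(out$rg_ratio, 0.2)
  expect_equal(exp(out$log_luminance), out$luminance)
  m$luminance <- -1
  expect_error(color_outcomes(m), "positive")
})

test_that("session calibration undoes exposure differences in generated studies", {
  cfg <- study_config()
  roster <- simulate_roster(cfg, seed = 21)
  col <- simulate_color(cfg, roster, seed = 22)
  capt <- expected_captures(synthetic_chart_reflectance(),
                            synthetic_receptor_model())
  measured <- col$photos |>
    dplyr::group_by(session_id) |>
    dplyr::group_split() |>
    purrr::map(function(ph) {
      chart <- dplyr::filter(col$charts, session_id == ph$session_id[1])
      measure_face(ph, fit_calibration(chart, capt))
    }) |>
    dplyr::bind_rows()
  # despite ~10% exposure swings, recovered captures track truth closely
  rel <- abs(measured$LW - measured$lw_true) / measured$lw_true
  expect_lt(median(rel), 0.05)
  expect_gt(stats::cor(measured$LW, measured$lw_true), 0.95)
})
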