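test_that("an exactly log-linear ladder fits with zero residuals", {
  map <- default_map()
  expect_equal(max(abs(map$residuals)), 0, tolerance = 1e-9)
  expect_equal(map$predict_row(62), 787.5 - 139 * log(62), tolerance = 1e-9)
  expect_equal(map$predict_kda(map$predict_row(62)), 62, tolerance = 1e-9)
})

test_that("a two-point ladder interpolates through both points", {
  map <- calibrate_migration(c(50, 300), c(100, 20))
  expect_equal(map$predict_row(100), 50, tolerance = 1e-9)
  expect_equal(map$predict_row(20), 300, tolerance = 1e-9)
})

test_that("a jittered ladder recovers the rendering slope within 5%", {
  w <- c(250, 150, 100, 75, 50, 37)
  set.seed(14)
  rows <- migration_row(w, c(787.5, -139)) + rnorm(6, 0, 2)
  map <- calibrate_migration(rows, w)
  expect_lt(abs(map$slope - (-139)) / 139, 0.05)
})

test_that("degenerate ladders are rejected", {
  expect_error(calibrate_migration(100, 50), "at least 2")
  expect_error(calibrate_migration(c(100, 200), c(20, 100)), "decrease")
})

test_that("corrected intensities recover programmed 1:2:4 amounts within 1%", {
  lanes <- lapply(1:3, function(i)
    list(id = paste0("L", i), bands = data.frame(kda = 62, amount = c(100, 200, 400)[i])))
  g <- render_gel(gel_scene_params(lanes, noise_sd = 0))
  map <- default_map()
  v <- sapply(paste0("L", 1:3), function(id)
    quantify_band(g$image, g$layout$lane_cols[[id]], 62, map, "bright",
                  g$layout$lane_cols)$corrected_intensity)
  expect_equal(unname(v[2] / v[1]), 2, tolerance = 0.01)
  expect_equal(unname(v[3] / v[1]), 4, tolerance = 0.01)
})

test_that("a zero-amount band measures zero and is flagged below detection", {
  lanes <- list(list(id = "z", bands = data.frame(kda = 62, amount = 0)))
  g <- render_gel(gel_scene_params(lanes, noise_sd = 0.005, seed = 3))
  b <- quantify_band(g$image, g$layout$lane_cols[["z"]], 62, default_map(),
                     "bright", g$layout$lane_cols)
  expect_identical(b$flags, "below-detection")
  ## at most a noise floor above zero
  expect_lt(b$corrected_intensity, 3)
})

test_that("corrected intensities are invariant to a global additive background", {
  lanes <- list(list(id = "z", bands = data.frame(kda = 62, amount = 300)))
  map <- default_map()
  v <- sapply(c(0.1, 0.25, 0.4), function(bg) {
    g <- render_gel(gel_scene_params(lanes, noise_sd = 0.005,
                                     background_level = bg, seed = 5))
    quantify_band(g$image, g$layout$lane_cols[["z"]], 62, map, "bright",
                  g$layout$lane_cols)$corrected_intensity
  })
  expect_lt(max(abs(v - v[1])) / v[1], 0.01)
})

test_that("corrected intensities shift < 5% under a rendered background gradient", {
  lanes <- list(list(id = "z", bands = data.frame(kda = 62, amount = 300)))
  map <- default_map()
  v <- sapply(c(0, 0.15), function(gr) {
    g <- render_gel(gel_scene_params(lanes, noise_sd = 0.005,
                                     background_gradient = gr, seed = 6))
    quantify_band(g$image, g$layout$lane_cols[["z"]], 62, map, "bright",
                  g$layout$lane_cols)$corrected_intensity
  })
  expect_lt(abs(v[2] - v[1]) / v[1], 0.05)
})

test_that("quantifying the inverted image with inverted polarity is identical", {
  lanes <- list(list(id = "z", bands = data.frame(kda = c(62, 72), amount = c(150, 400))))
  map <- default_map()
  gb <- render_gel(gel_scene_params(lanes, polarity = "bright", seed = 7))
  gd <- render_gel(gel_scene_params(lanes, polarity = "dark", seed = 7))
  for (k in c(62, 72)) {
    b1 <- quantify_band(gb$image, gb$layout$lane_cols[["z"]], k, map, "bright",
                        gb$layout$lane_cols)
    b2 <- quantify_band(gd$image, gd$layout$lane_cols[["z"]], k, map, "dark",
                        gd$layout$lane_cols)
    expect_equal(b1$corrected_intensity, b2$corrected_intensity, tolerance = 1e-12)
  }
})

test_that("housekeeping ratios divide corrected intensities", {
  mk <- function(ci, flags = "") data.frame(corrected_intensity = ci, flags = flags)
  expect_equal(housekeeping_ratio(mk(50), mk(100)), 0.5)
  t1 <- mk(123.4)
  expect_equal(housekeeping_ratio(t1, t1), 1.0)
  r <- housekeeping_ratio(mk(50), mk(0))
  expect_true(is.na(r))
  expect_identical(attr(r, "flag"), "tubulin-below-detection")
})

test_that("a rendered target/control pair recovers the programmed ratio within 2%", {
  lanes <- list(list(id = "z",
                     bands = data.frame(kda = c(42, 52), amount = c(120, 300))))
  g <- render_gel(gel_scene_params(lanes, noise_sd = 0.003,
                                   background_gradient = 0.05, seed = 8))
  map <- default_map()
  a <- quantify_band(g$image, g$layout$lane_cols[["z"]], 42, map, "bright",
                     g$layout$lane_cols)
  tub <- quantify_band(g$image, g$layout$lane_cols[["z"]], c(50, 55), map, "bright",
                       g$layout$lane_cols)
  expect_equal(housekeeping_ratio(a, tub), 120 / 300, tolerance = 0.02)
})

test_that("the MMP2 active fraction behaves at interior and boundary values", {
  mk <- function(ci) data.frame(corrected_intensity = ci, flags = "")
  expect_equal(mmp2_active_fraction(mk(30), mk(70)), 0.30)
  expect_equal(mmp2_active_fraction(mk(10), mk(0)), 1.0)
  f <- mmp2_active_fraction(mk(0), mk(0))
  expect_true(is.na(f))
  ## invariance to common rescaling
  expect_equal(mmp2_active_fraction(mk(3e4), mk(7e4)), 0.30)
})

test_that("a rendered zymograph lane recovers a programmed 0.2 active fraction", {
  lanes <- list(list(id = "z", bands = data.frame(kda = c(62, 72), amount = c(200, 800))))
  g <- render_gel(gel_scene_params(lanes, noise_sd = 0.005, seed = 9))
  map <- default_map()
  a <- quantify_band(g$image, g$layout$lane_cols[["z"]], 62, map, "bright",
                     g$layout$lane_cols)
  p <- quantify_band(g$image, g$layout$lane_cols[["z"]], 72, map, "bright",
                     g$layout$lane_cols)
  expect_equal(mmp2_active_fraction(a, p), 0.2, tolerance = 0.1)
  expect_lt(abs(mmp2_active_fraction(a, p) - 0.2), 0.02)
})

test_that("Tukey-fence outliers handle degenerate and identical data", {
  f <- loading_outliers(c(1, 1, 1, 1, 100))
  expect_identical(as.logical(f), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(attr(f, "fences"), c(1, 1))
  expect_false(any(loading_outliers(rep(7, 10))))
  expect_error(loading_outliers(c(1, 2, 3)), "at least 4")
})

test_that("Tukey-fence flags match the brute-force quartile oracle", {
  set.seed(33)
  for (rep in 1:20) {
    x <- rlnorm(sample(4:200, 1), 4, 0.5)
    expect_identical(as.logical(loading_outliers(x)), oracle_tukey_outliers(x))
  }
})
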