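test_that("pixel counts convert to absolute areas", {
  expect_equal(pixels_to_area(100, 10), 0.01)
  expect_equal(pixels_to_area(0, 10), 0)
  expect_equal(pixels_to_area(1, 1), 1e-6)
  expect_error(pixels_to_area(-5, 10), "negative")
})

test_that("strategy A recovers ground-truth area on a noise-free frame", {
  sc <- quick_scene(seed = 3, noise_sd = 0)
  rt <- render_timelapse(sc)
  for (i in 1:2) {
    fr <- image_frame(rt$frames[[i]], sc$pixel_size, rt$times[i])
    sg <- segment_strategy_a(fr)
    expect_length(sg$quality_flags, 0)
    expect_lt(abs(sg$area_mm2 - rt$areas_mm2[i]) / rt$areas_mm2[i], 0.02)
  }
})

test_that("strategy A flags an all-background frame as empty", {
  fr <- image_frame(matrix(0.85, 64, 64), pixel_size = 12)
  sg <- segment_strategy_a(fr)
  ## constant frame: auto threshold cannot separate classes
  expect_true("degenerate-threshold" %in% sg$quality_flags)
  fr2 <- image_frame(matrix(0.85 + rnorm(64 * 64, 0, 0.01), 64, 64), pixel_size = 12)
  sg2 <- segment_strategy_a(fr2)
  expect_gt(length(sg2$quality_flags), 0)
})

test_that("strategy A flags a frame where tissue swallows 95% of pixels", {
  x <- matrix(0.35, 100, 100)
  x[1:5, ] <- 0.9   # thin background strip
  fr <- image_frame(x, 12)
  sg <- segment_strategy_a(fr)
  expect_true(any(c("implausible-area", "touches-border") %in% sg$quality_flags))
})

test_that("strategy B tolerates a strong illumination gradient", {
  sc <- quick_scene(seed = 4, illumination_gradient = 0.6)
  rt <- render_timelapse(sc)
  for (i in 1:2) {
    fr <- image_frame(rt$frames[[i]], sc$pixel_size, rt$times[i])
    sg <- segment_strategy_b(fr)
    expect_lt(abs(sg$area_mm2 - rt$areas_mm2[i]) / rt$areas_mm2[i], 0.05)
  }
})

test_that("strategy B flags a constant frame as degenerate", {
  fr <- image_frame(matrix(0.5, 64, 64), 12)
  sg <- segment_strategy_b(fr)
  expect_true("degenerate-threshold" %in% sg$quality_flags)
})

test_that("strategies A and B agree on a clean high-contrast frame", {
  sc <- quick_scene(seed = 5, noise_sd = 0)
  fr <- render_frame(sc, 1)
  a <- segment_strategy_a(fr)
  b <- segment_strategy_b(fr)
  expect_lt(abs(a$area_mm2 - b$area_mm2) / a$area_mm2, 0.03)
})

test_that("fallback picks A on clean frames, B on corrupted, fails on constant", {
  clean <- render_frame(quick_scene(seed = 6))
  expect_identical(segment_frame(clean)$strategy_used, "A")
  corrupted <- render_frame(quick_scene(seed = 6, illumination_gradient = 0.6))
  expect_identical(segment_frame(corrupted)$strategy_used, "B")
  flat <- image_frame(matrix(0.5, 64, 64), 12)
  res <- segment_frame(flat)
  expect_identical(res$strategy_used, "none")
  expect_true(any(grepl("^A:", res$quality_flags)))
  expect_true(any(grepl("^B:", res$quality_flags)))
})

test_that("segmentation is deterministic and masks are single filled components", {
  fr <- render_frame(quick_scene(seed = 9))
  r1 <- segment_frame(fr)
  r2 <- segment_frame(fr)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$area_mm2, r2$area_mm2)
  lab <- label_components(r1$mask, 8)
  expect_equal(max(lab), 1L)
  expect_identical(unname(fill_holes(r1$mask)), unname(r1$mask))
  expect_equal(r1$pixel_count, sum(r1$mask))
  expect_equal(r1$area_mm2, pixels_to_area(r1$pixel_count, fr$pixel_size))
})

test_that("strategy A reproduces the exact mask on a binary-valued fixture", {
  ## noise-free two-level frame built from a rendered ground-truth mask
  sc <- quick_scene(seed = 11, noise_sd = 0, boundary_softness = 1e-6)
  rt <- render_timelapse(sc)
  gt <- rt$masks[[1]]
  x <- matrix(0.85, nrow(gt), ncol(gt)); x[gt] <- 0.35
  sg <- segment_strategy_a(image_frame(x, sc$pixel_size))
  expect_identical(unname(sg$mask), unname(fill_holes(gt)))
})
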