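make_series <- function(areas, times = c(0, 48), flags = rep("", length(times))) {
  area_series("t1", times, areas, flags)
}

test_that("relative area is the 48 h / 0 h percentage", {
  expect_equal(relative_area(make_series(c(2.0, 0.7))), 35.0)
  expect_equal(relative_area(make_series(c(1.23, 1.23))), 100.0)
})

test_that("relative area is invariant to a common area rescaling", {
  s1 <- make_series(c(2.0, 0.7))
  for (c_ in c(0.1, 3, 1000)) {
    s2 <- make_series(c(2.0, 0.7) * c_)
    expect_equal(relative_area(s2), relative_area(s1))
  }
})

test_that("relative area uses nearest frames within one hour and rejects flagged ones", {
  s <- area_series("t", c(0, 24, 47.5), c(2, 1.2, 0.8))
  expect_equal(relative_area(s), 40)
  expect_error(relative_area(area_series("t", c(0, 30), c(2, 1))), "within")
  expect_error(relative_area(make_series(c(2, 1), flags = c("no-tissue", ""))),
               "flagged")
  expect_error(relative_area(make_series(c(0, 1))), "zero area")
})

test_that("noise-free rendered series matches the closed-form decay ratio", {
  sc <- tissue_scene_params(n_frames = 2L, frame_interval = 48, noise_sd = 0, seed = 2)
  rt <- render_timelapse(sc)
  fr <- lapply(1:2, function(i) image_frame(rt$frames[[i]], sc$pixel_size, rt$times[i]))
  ser <- endpoint_series(fr[[1]], fr[[2]])
  want <- 100 * compaction_area(48, 4, 1.6, 0.08) / compaction_area(0, 4, 1.6, 0.08)
  expect_lt(abs(relative_area(ser) - want) / want, 0.03)
})

test_that("a programmed release is classified with the right time", {
  sc <- tissue_scene_params(release_time = 20, seed = 7)
  rt <- render_timelapse(sc)
  ser <- area_series("t7", rt$times, rt$areas_mm2)
  res <- classify_release(ser, rt$masks, sc$post_layout)
  expect_identical(res$status, "released")
  expect_lte(abs(res$release_time_h - 20), 1)
  expect_true(is.na(res$relative_area_pct))
})

test_that("a monotone compaction scene stays intact", {
  sc <- tissue_scene_params(seed = 8)
  rt <- render_timelapse(sc)
  ser <- area_series("t8", rt$times, rt$areas_mm2)
  res <- classify_release(ser, rt$masks, sc$post_layout)
  expect_identical(res$status, "intact")
  expect_true(is.na(res$release_time_h))
  expect_gt(res$relative_area_pct, 0)
})

test_that("classification is refused without masks or post layout", {
  sc <- tissue_scene_params(n_frames = 3L, frame_interval = 24, seed = 9)
  rt <- render_timelapse(sc)
  ser <- area_series("t9", rt$times, rt$areas_mm2)
  expect_error(classify_release(ser, NULL, sc$post_layout), "masks")
  expect_error(classify_release(ser, rt$masks, NULL), "refused")
  expect_error(classify_release(ser, rt$masks[1:2], sc$post_layout), "one mask per frame")
})

test_that("a detached 48 h endpoint frame classifies as released", {
  sc <- tissue_scene_params(n_frames = 2L, frame_interval = 48,
                            release_time = 30, seed = 10)
  rt <- render_timelapse(sc)
  fr <- lapply(1:2, function(i) image_frame(rt$frames[[i]], sc$pixel_size, rt$times[i]))
  ser <- endpoint_series(fr[[1]], fr[[2]])
  res <- classify_release(ser, attr(ser, "masks"), sc$post_layout)
  expect_identical(res$status, "released")
})

test_that("a 0 h frame failing both strategies flags the series", {
  flat <- image_frame(matrix(0.5, 64, 64), 12, timestamp = 0)
  ok <- render_frame(quick_scene(seed = 11), 2)
  ser <- endpoint_series(flat, image_frame(ok$data, ok$pixel_size, 48))
  expect_true(nzchar(ser$flags[1]))
  expect_error(relative_area(ser), "flagged")
})

test_that("detachment already at 0 h is flagged as pre-release", {
  sc <- tissue_scene_params(release_time = 0, seed = 12)
  rt <- render_timelapse(sc)
  ser <- area_series("t12", rt$times, rt$areas_mm2)
  res <- classify_release(ser, rt$masks, sc$post_layout)
  expect_identical(res$status, "released")
  expect_equal(res$release_time_h, 0)
  expect_true("pre-release" %in% res$flags)
})

test_that("series invariants are enforced", {
  expect_error(area_series("t", c(0, 0), c(1, 1)), "increasing")
  expect_error(area_series("t", c(1, 2), c(1, 1)), "start at 0")
  expect_error(area_series("t", 0, 1), "at least 2")
})
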