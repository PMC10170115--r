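test_that("a still tube maps to a constant diameter everywhere", {
  vid <- generate_motility_video(length_mm = 8, duration_s = 30,
                                 ripples = NULL, noise_sd = 0, seed = 1)
  stm <- compute_stm(vid)
  expect_true(all(stm$valid))
  expect_lte(diff(range(stm$diameter)), vid$pixel_size)
  expect_lte(max(abs(stm$diameter - 2000)), vid$pixel_size)
})

test_that("the extracted STM matches the analytic diameter field within a pixel", {
  vid <- generate_motility_video(length_mm = 15, duration_s = 90, seed = 2)
  stm <- compute_stm(vid)
  tr <- ground_truth(vid)
  expect_lte(max(abs(stm$diameter - tr$diameter)), vid$pixel_size + 1e-9)
  expect_equal(dim(stm$diameter), dim(tr$diameter))
})

test_that("empty frames raise an STM quality error", {
  frames <- array(0.9, c(20, 30, 5))
  expect_error(compute_stm(frames, pixel_size = 40, frame_rate = 3.75),
               "quality")
})

test_that("an occluding wave is rejected at generation", {
  expect_error(
    generate_motility_video(duration_s = 30,
                            ripples = list(amplitude = 2100), seed = 3),
    "occlusion")
})

test_that("STM round-trips through TIFF + JSON and tidies to long format", {
  vid <- generate_motility_video(length_mm = 8, duration_s = 20, seed = 4)
  stm <- compute_stm(vid)
  path <- tempfile(fileext = ".tif")
  write_stm(stm, path)
  back <- read_stm(path)
  expect_equal(back$diameter, stm$diameter, tolerance = 1e-5)
  expect_equal(back$frame_rate, stm$frame_rate)
  td <- tidy(stm)
  expect_identical(nrow(td), length(stm$diameter))
  expect_named(td, c("time", "position", "diameter"))
})
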