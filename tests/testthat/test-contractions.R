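single_wave_video <- function(direction = "distal", velocity = 1000,
                              onset = 10, duration_s = 60, seed = 1) {
  generate_motility_video(
    duration_s = duration_s, ripples = NULL,
    neurogenic = list(onsets = onset, velocity = velocity,
                      direction = direction),
    seed = seed)
}

test_that("a constant STM yields no events and a low-activity summary", {
  vid <- generate_motility_video(length_mm = 8, duration_s = 90,
                                 ripples = NULL, seed = 1)
  stm <- compute_stm(vid)
  ev <- detect_contractions(stm)
  expect_identical(nrow(ev), 0L)
  cls <- classify_pattern(ev, stm)
  expect_identical(cls$label, "ripples_only")
  expect_true(cls$low_activity)
  expect_equal(cls$ripple_freq, 0)
})

test_that("single waves are detected with the right direction and velocity", {
  for (dirn in c("distal", "proximal")) {
    vid <- single_wave_video(dirn, velocity = 1000, seed = 2)
    ev <- detect_contractions(compute_stm(vid))
    expect_identical(nrow(ev), 1L)
    expect_identical(ev$direction, dirn)
    expect_lt(abs(ev$velocity - 1000) / 1000, 0.1)
    expect_lt(abs(ev$onset - 10), 2)
  }
})

test_that("a bidirectional event keeps one origin and two branch velocities", {
  vid <- generate_motility_video(
    duration_s = 60, ripples = NULL,
    neurogenic = NULL, seed = 3)
  # inject one central ripple via the ripple pathway at a known origin:
  vid2 <- generate_motility_video(
    duration_s = 60,
    ripples = list(rate_per_min = 1, jitter_s = 0, velocity = 1500),
    seed = 4)
  stm <- compute_stm(vid2)
  tr <- ground_truth(vid2)$events
  ev <- detect_contractions(stm)
  bi <- ev[ev$direction == "bidirectional", ]
  expect_gte(nrow(bi), 1L)
  d0 <- min(abs(bi$origin - tr$origin[1]))
  expect_lte(d0, 2 * stm$bin_size)
  expect_lt(abs(bi$velocity[1] - 1500) / 1500, 0.25)
})

test_that("reversing time maps distal events to proximal ones", {
  vid <- single_wave_video("distal", seed = 5)
  stm_f <- compute_stm(vid)
  rev_frames <- vid$frames[, , rev(seq_len(dim(vid$frames)[3]))]
  stm_r <- compute_stm(rev_frames, pixel_size = vid$pixel_size,
                       frame_rate = vid$frame_rate)
  ev_f <- detect_contractions(stm_f)
  ev_r <- detect_contractions(stm_r)
  expect_identical(nrow(ev_f), nrow(ev_r))
  expect_identical(ev_f$direction, "distal")
  expect_identical(ev_r$direction, "proximal")
  expect_lt(abs(ev_f$velocity - ev_r$velocity) / ev_f$velocity, 0.05)
})

test_that("ripple frequency recovers the generated rate", {
  vid <- generate_motility_video(duration_s = 240, seed = 6)
  stm <- compute_stm(vid)
  expect_lt(abs(ripple_frequency(stm) - 6), 0.5)
  short <- compute_stm(generate_motility_video(length_mm = 8,
                                               duration_s = 30,
                                               ripples = NULL, seed = 7))
  expect_error(ripple_frequency(short), "shorter")
})

test_that("comparing an STM with itself gives zero deltas", {
  vid <- generate_motility_video(duration_s = 120, seed = 8)
  stm <- compute_stm(vid)
  cmp <- compare_conditions(stm, stm)
  expect_equal(cmp$ripple_freq_change, 0)
  expect_equal(cmp$quiescent_change, 0)
  expect_identical(cmp$label_from, cmp$label_to)
  other <- compute_stm(generate_motility_video(length_mm = 8,
                                               duration_s = 90,
                                               pixel_size = 40, seed = 9))
  expect_error(compare_conditions(stm, other), "calibration")
})
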