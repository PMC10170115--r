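test_that("area-based counting follows total area / unit area exactly", {
  empty <- matrix(FALSE, 50, 50)
  expect_identical(estimate_neuron_count_by_area(empty, pixel_size = 1), 0)
  one <- matrix(FALSE, 50, 50)
  one[seq_len(138)] <- TRUE   # exactly 138 um^2 at 1 um/px
  expect_equal(estimate_neuron_count_by_area(one, pixel_size = 1), 1)
  expect_equal(estimate_neuron_count_by_area(one, unit_area = 69,
                                             pixel_size = 1), 2)
  expect_error(estimate_neuron_count_by_area(one, unit_area = 0,
                                             pixel_size = 1), "positive")
})

test_that("area-based count recovers the true n on calibrated renders", {
  errs <- vapply(1:5, function(s) {
    p <- generate_point_pattern("csr", 150, d_min = 15, margin = 10,
                                depth_stripe = 0, seed = s)
    stk <- render_wholemount(p, seed = s + 40)
    estimate_neuron_count_by_area(stk) / 150 - 1
  }, numeric(1))
  expect_true(all(abs(errs) < 0.1))
})

test_that("colocalizing a channel with itself counts its own components", {
  centres <- data.frame(x = c(40, 100, 160, 60), y = c(40, 80, 120, 160))
  stk <- disk_stack(centres)
  expect_identical(colocalize(stk, stk), 4L)
})

test_that("an empty subtype channel colocalizes to zero", {
  centres <- data.frame(x = c(40, 100), y = c(40, 80))
  ref <- disk_stack(centres)
  empty <- image_stack(list(huc = matrix(0, 200, 200)), 1)
  expect_identical(colocalize(ref, empty), 0L)
  bad <- image_stack(list(huc = matrix(0, 60, 60)), 1)
  expect_error(colocalize(ref, bad), "shape")
})

test_that("subtype fractions divide double-positives by the area estimate", {
  p <- generate_point_pattern("csr", 100, d_min = 15, margin = 10,
                              depth_stripe = 0, seed = 21)
  p <- assign_subtypes(p, c(calr = 0.4), seed = 22)
  stk <- render_wholemount(p, seed = 23)
  ref <- image_stack(stk$channels["huc"], 1)
  sub <- image_stack(stk$channels["calr"], 1)
  sf <- subtype_fraction(ref, sub)
  expect_identical(sf$double_positive, 40L)
  expect_lt(abs(sf$fraction - 0.4), 0.05)
  # empty subtype: fraction 0; empty reference: flagged undefined
  sf0 <- subtype_fraction(ref, image_stack(list(x = matrix(0, 800, 800)), 1))
  expect_equal(sf0$fraction, 0)
  sfu <- subtype_fraction(image_stack(list(x = matrix(0, 800, 800)), 1), sub)
  expect_true(is.na(sfu$fraction))
  expect_identical(sfu$flag, "undefined")
})

test_that("a polygonal roi restricts both masks", {
  centres <- data.frame(x = c(40, 160), y = c(40, 160))
  stk <- disk_stack(centres)
  # roi covering only the first disk
  sf <- subtype_fraction(stk, stk, unit_area = pi * 6.63^2,
                         roi = c(0, 0, 100, 100))
  expect_identical(sf$double_positive, 1L)
  expect_lt(abs(sf$total_estimate - 1), 0.2)
  expect_error(subtype_fraction(stk, stk, roi = c(0, 0, 500, 500)),
               "outside")
})
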