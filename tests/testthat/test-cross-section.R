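test_that("bands are constructed at the requested thickness", {
  cs <- render_cross_section(pixel_size = 0.5, noise = NULL, seed = 1)
  # CM thickness 30 um at 0.5 um/px: band exactly 60 px tall
  sma <- cs$channels$sma[, , 1]
  col <- sma[, 100]
  runs <- rle(col > 0.5)
  expect_identical(runs$lengths[runs$values][1], 60L)
  expect_error(render_cross_section(layers = c(mucosa = -1, smp = 30, cm = 30,
                                               mp = 40, lm = 25)),
               "positive")
})

test_that("muscle thickness is recovered within a pixel on both layers", {
  cs <- render_cross_section(seed = 2)
  expect_lt(abs(measure_muscle_thickness(cs, "cm") - 30), 1 + 1e-9)
  expect_lt(abs(measure_muscle_thickness(cs, "lm") - 25), 1 + 1e-9)
  tr <- attr(measure_muscle_thickness(cs, "cm", n_locations = 4), "transects")
  expect_length(tr, 4)
})

test_that("a transect without two muscle bands raises a named error", {
  one_band <- matrix(0, 200, 100)
  one_band[50:80, ] <- 1
  expect_error(measure_muscle_thickness(one_band, "lm", pixel_size = 1),
               "transect 1")
})

test_that("nucleus counts follow the Poisson draw stored in ground truth", {
  cs <- render_cross_section(width = 2000, nucleus_density = 5e-4, seed = 3)
  tr <- ground_truth(cs)
  nd <- nuclear_density(cs, roi = tr$mp_roi, channel = "sox10")
  expect_identical(nd$count, tr$n_nuclei)
  expect_equal(nd$density, tr$n_nuclei / (tr$layers[["mp"]] * 2000))
  expect_error(nuclear_density(cs, roi = c(0, 0, 99999, 10)), "outside")
})

test_that("zero apoptotic fraction leaves the caspase channel empty", {
  cs <- render_cross_section(apoptotic_fraction = 0, noise = NULL, seed = 4)
  expect_equal(sum(cs$channels$caspase), 0)
  cs2 <- render_cross_section(n_neurons = 40, apoptotic_fraction = 0.1,
                              noise = NULL, seed = 5)
  expect_identical(ground_truth(cs2)$n_apoptotic, 4L)
  expect_gt(sum(cs2$channels$caspase), 0)
})

test_that("apoptotic fractions are recovered from the MP region of interest", {
  cs <- render_cross_section(width = 8000, n_neurons = 500,
                             apoptotic_fraction = 0.006, seed = 6)
  tr <- ground_truth(cs)
  sf <- subtype_fraction(image_stack(cs$channels["huc"], 1),
                         image_stack(cs$channels["caspase"], 1),
                         roi = tr$mp_roi)
  expect_identical(sf$double_positive, tr$n_apoptotic)
  expect_lt(sf$fraction, 0.012)
})
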