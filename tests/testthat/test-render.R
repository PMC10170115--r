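test_that("an empty pattern renders to a background-only stack", {
  p <- generate_point_pattern("csr", 0, seed = 1)
  stk <- render_wholemount(p, seed = 2)
  expect_s3_class(stk, "image_stack")
  expect_equal(dim(stk$channels$huc)[1:2], c(800, 800))
  expect_equal(stk$z_step, 3)
  # noise floor only: nothing approaching soma intensity
  expect_lt(max(stk$channels$huc), 0.5)
})

test_that("defaults give the standard field size and z spacing", {
  p <- generate_point_pattern("csr", 5, seed = 3)
  stk <- render_wholemount(p, seed = 4)
  expect_equal(dim(stk$channels$huc)[1:2] * stk$pixel_size, c(800, 800))
  expect_equal(stk$z_step, 3)
})

test_that("a coarse pixel grid that cannot resolve a soma is rejected", {
  p <- generate_point_pattern("csr", 5, seed = 3)
  expect_error(
    suppressWarnings(render_wholemount(p, soma_area = 20, pixel_size = 4)),
    "2 px")
})

test_that("rendered foreground area per soma stays near the nominal soma area", {
  p <- generate_point_pattern("csr", 60, d_min = 15, margin = 10, seed = 5)
  stk <- render_wholemount(p, seed = 6)
  fg <- enteromap:::foreground_mask(stk, blur_sigma = 1)
  per_soma <- sum(fg$mask) * fg$pixel_size^2 / nrow(p)
  expect_lt(abs(per_soma - 138) / 138, 0.1)
})

test_that("subtype channels contain exactly the labelled somata", {
  p <- generate_point_pattern("csr", 80, d_min = 15, margin = 10, seed = 7)
  p <- assign_subtypes(p, c(calr = 0.25), seed = 8)
  stk <- render_wholemount(p, noise = NULL, seed = 9)
  seg <- segment_neurons(image_stack(stk$channels["calr"], stk$pixel_size))
  expect_identical(nrow(seg$centroids), sum(p$calr))
  d <- match_distances(p[p$calr, ], seg$centroids)
  expect_lt(max(d), 1)
})
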