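test_that("single-slice stacks project to depth zero everywhere in foreground", {
  centres <- data.frame(x = 50, y = 50)
  stk <- disk_stack(centres, dim_um = c(100, 100))
  dp <- depth_projection(stk)
  expect_true(all(dp[!is.na(dp)] == 0))
  expect_true(any(is.na(dp)))
})

test_that("slice placement converts to micrometre depths via the z-step", {
  p <- as_ens_pattern(
    tibble::tibble(x = c(50, 150), y = c(50, 150), depth = c(0, 12)),
    window = c(200, 200))
  stk <- render_wholemount(p, noise = NULL, seed = 1)
  dp <- depth_projection(stk, threshold = 0.3)
  d <- soma_depths(dp, p, stk$pixel_size)
  expect_equal(d, c(0, 12))
})

test_that("depth projection is invariant to uniform intensity scaling", {
  p <- generate_point_pattern("grid", 60, margin = 8, seed = 41)
  stk <- render_wholemount(p, n_slices = 7, seed = 42)
  stk3 <- image_stack(lapply(stk$channels, function(a) a * 3),
                      stk$pixel_size, stk$z_step)
  expect_identical(depth_projection(stk), depth_projection(stk3))
})

test_that("stripe and bridging somata separate into two depth classes", {
  p <- generate_point_pattern("grid", 200, margin = 8, seed = 43)
  stk <- render_wholemount(p, n_slices = 7, seed = 44)
  dp <- depth_projection(stk)
  d <- soma_depths(dp, p, stk$pixel_size)
  # bimodal: very few somata read back at intermediate depths
  expect_lt(mean(d > 5 & d < 13, na.rm = TRUE), 0.1)
  cls <- classify_depth(d, class_depths = c(3, 15))
  truth <- ifelse(ground_truth(p)$classes == "bridge", "deep", "shallow")
  expect_gte(mean(cls == truth, na.rm = TRUE), 0.95)
})
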