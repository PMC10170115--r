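test_that("constant images give an empty result with a warning, not an error", {
  m <- matrix(0, 100, 100)
  expect_warning(seg <- segment_neurons(m, pixel_size = 1), "empty|constant")
  expect_identical(nrow(seg$centroids), 0L)
  expect_identical(seg$flag, "empty")
  expect_identical(nrow(as_pattern(seg)), 0L)
})

test_that("disks at known centres are recovered within a pixel", {
  centres <- data.frame(x = c(50, 120, 80), y = c(60, 100, 160))
  stk <- disk_stack(centres)
  seg <- segment_neurons(stk)
  expect_identical(nrow(seg$centroids), 3L)
  expect_lt(max(match_distances(centres, seg$centroids)), 1)
  # blurred Otsu masks run a little wide; the area stays in the right range
  expect_true(all(abs(seg$centroids$area - pi * 6.63^2) / (pi * 6.63^2) < 0.25))
})

test_that("watershed splits touching somata; without it they merge", {
  centres <- data.frame(x = c(90, 100), y = c(100, 100))  # 10 um apart
  stk <- disk_stack(centres)
  split <- segment_neurons(stk, split_touching = TRUE)
  merged <- segment_neurons(stk, split_touching = FALSE)
  expect_identical(nrow(split$centroids), 2L)
  expect_identical(nrow(merged$centroids), 1L)
})

test_that("objects below min_size are removed", {
  stk <- disk_stack(data.frame(x = 50, y = 50), radius = 2)  # ~12.6 um^2
  seg <- segment_neurons(stk, blur_sigma = 0, min_size = 20)
  expect_identical(nrow(seg$centroids), 0L)
  seg2 <- segment_neurons(stk, blur_sigma = 0, min_size = 5)
  expect_identical(nrow(seg2$centroids), 1L)
})

test_that("segmentation invariants hold on a rendered field", {
  p <- generate_point_pattern("csr", 120, d_min = 15, margin = 10, seed = 31)
  stk <- render_wholemount(p, seed = 32)
  seg <- segment_neurons(stk)
  expect_identical(nrow(seg$centroids), 120L)
  d <- match_distances(p, seg$centroids)
  expect_lt(sqrt(mean(d^2)), 1)
  expect_true(all(seg$centroids$area >= seg$params$min_size))
  expect_identical(nrow(tidy(seg)), 120L)
})
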