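test_that("null simulation is seeded, reproducible, and per-replicate streamed", {
  v1 <- simulate_null(100, n_sim = 3, seed = 5)
  v2 <- simulate_null(100, n_sim = 3, seed = 5)
  expect_identical(v1, v2)
  expect_length(v1, 3)
  expect_identical(anyDuplicated(attr(v1, "seeds")), 0L)
  # the first replicates are unchanged when more are requested
  v3 <- simulate_null(100, n_sim = 5, seed = 5)
  expect_equal(as.numeric(v3)[1:3], as.numeric(v1)[1:3])
  expect_error(simulate_null(100, n_sim = 1, seed = 1), "at least 2")
})

test_that("null ensembles are stable across master seeds", {
  a <- simulate_null(200, n_sim = 100, seed = 1)
  b <- simulate_null(200, n_sim = 100, seed = 2)
  se <- sqrt(sd(a)^2 / 100 + sd(b)^2 / 100)
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("leave-one-out z-scores are centred and spread like the ensemble", {
  set.seed(1)
  vals <- rnorm(200, 10, 2)
  z <- enteromap:::loo_z(vals)
  expect_equal(mean(z), 0, tolerance = 0.02)
  expect_equal(sd(z), 1, tolerance = 0.05)
  # removing the scored sample avoids shrinking its own z
  expect_gt(max(abs(z)), max(abs(scale(vals))))
})

test_that("striped data score above the null band, CSR data inside it", {
  ps <- generate_point_pattern("striped", 300, seed = 21)
  zs <- zscore_difference(ps, n_sim = 60, seed = 22)
  expect_gt(zs$z_diff, zs$band[2])
  pc <- generate_point_pattern("csr", 300, seed = 23)
  zc <- zscore_difference(pc, n_sim = 60, seed = 24)
  expect_lt(abs(zc$z_diff), 3)
  g <- glance(zs)
  expect_true(g$outside_band)
  expect_equal(g$z_diff, zs$z_diff)
  td <- tidy(zs)
  expect_identical(nrow(td), 60L)
  expect_equal(mean(td$z), 0, tolerance = 0.05)
})

test_that("single-point patterns and degenerate nulls raise errors", {
  p1 <- as_ens_pattern(data.frame(x = 5, y = 5), c(800, 800))
  expect_error(zscore_difference(p1), "insufficient")
})

test_that("z-score results are reproducible under the same seed", {
  p <- generate_point_pattern("csr", 150, seed = 31)
  a <- zscore_difference(p, n_sim = 20, seed = 32)
  b <- zscore_difference(p, n_sim = 20, seed = 32)
  expect_identical(a$z_diff, b$z_diff)
  expect_identical(a$null_values, b$null_values)
})
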