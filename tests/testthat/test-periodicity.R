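test_that("stripe period and orientation are recovered from the CIF", {
  p <- generate_point_pattern("striped", 300, seed = 1)
  cif <- suppressWarnings(compute_cif(p, L = 400))
  per <- stripe_periodicity(cif)
  expect_true(per$significant)
  expect_lt(abs(per$period - 150), 15)
  expect_identical(per$orientation, "circumferential_stripes")
  expect_false(per$at_range_limit)
})

test_that("rotated stripes are attributed to the other axis", {
  p <- generate_point_pattern("striped", 300, orientation = "longitudinal",
                              seed = 2)
  per <- stripe_periodicity(suppressWarnings(compute_cif(p, L = 400)))
  expect_true(per$significant)
  expect_identical(per$orientation, "longitudinal_stripes")
  expect_lt(abs(per$period - 150), 15)
})

test_that("CSR patterns are mostly not flagged periodic", {
  flags <- vapply(1:12, function(s) {
    p <- generate_point_pattern("csr", 300, seed = s + 100)
    stripe_periodicity(compute_cif(p))$significant
  }, logical(1))
  expect_lte(sum(flags), 3)
})

test_that("a period near the map extent is flagged at the range limit", {
  # one cycle across the positive-lag half: period ~ L
  p <- generate_point_pattern("striped", 300, stripe_period = 380,
                              stripe_width = 100, seed = 3)
  per <- stripe_periodicity(suppressWarnings(compute_cif(p, L = 360)))
  expect_true(per$at_range_limit)
  cif_small <- compute_cif(generate_point_pattern("csr", 50, seed = 4),
                           L = 8, bin = 4)
  expect_error(stripe_periodicity(cif_small), "below one candidate")
})
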