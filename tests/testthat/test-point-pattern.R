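test_that("empty request gives an empty pattern with intact metadata", {
  p <- generate_point_pattern("csr", 0, seed = 1)
  expect_s3_class(p, "ens_pattern")
  expect_identical(nrow(p), 0L)
  expect_equal(attr(p, "window"), c(800, 800))
})

test_that("hard-core CSR respects the window, the exclusion distance, and the seed", {
  p1 <- generate_point_pattern("csr", 300, d_min = 5, seed = 1)
  p2 <- generate_point_pattern("csr", 300, d_min = 5, seed = 1)
  p3 <- generate_point_pattern("csr", 300, d_min = 5, seed = 2)
  expect_identical(nrow(p1), 300L)
  expect_identical(p1$x, p2$x)
  expect_identical(p1$y, p2$y)
  expect_false(identical(p1$x, p3$x))
  expect_true(all(p1$x >= 0 & p1$x < 800 & p1$y >= 0 & p1$y < 800))
  # exhaustive pairwise check against the brute-force oracle
  expect_gte(min_dist_oracle(p1$x, p1$y), 5)
  expect_equal(min_pair_distance(p1), min_dist_oracle(p1$x, p1$y))
})

test_that("hard-core holds across modes and point counts", {
  for (mode in c("csr", "striped", "grid")) {
    for (n in c(50, 400)) {
      p <- generate_point_pattern(mode, n, d_min = 5, seed = n)
      expect_gte(min_pair_distance(p), 5)
    }
  }
})

test_that("striped patterns put the nominal fraction of points in bands", {
  fracs <- vapply(1:10, function(s) {
    p <- generate_point_pattern("striped", 300, stripe_period = 150,
                                stripe_width = 40, p_in = 0.9, seed = s)
    mean((p$y %% 150) < 40)
  }, numeric(1))
  expect_true(all(abs(fracs - 0.9) <= 0.05))
})

test_that("grid mode adds deeper bridging points between stripes", {
  p <- generate_point_pattern("grid", 300, bridge_frac = 0.25, seed = 7)
  expect_identical(sum(p$class == "bridge"), 75L)
  expect_setequal(unique(p$depth), c(3, 15))
  expect_true(all(p$depth[p$class == "bridge"] == 15))
  # bridging points concentrate between the bands
  expect_lt(mean((p$y[p$class == "bridge"] %% 150) < 40), 0.3)
})

test_that("orientation parameter flips the periodic axis", {
  p <- generate_point_pattern("striped", 300, orientation = "longitudinal",
                              seed = 3)
  expect_gte(mean((p$x %% 150) < 40), 0.85)
})

test_that("infeasible packing and bad arguments raise errors", {
  expect_error(generate_point_pattern("csr", 300, window = c(40, 40),
                                      d_min = 5, seed = 1),
               "packing")
  expect_error(generate_point_pattern("blob", 10), "arg")
  expect_error(generate_point_pattern("csr", -3), "non-negative")
  expect_error(as_ens_pattern(data.frame(x = 900, y = 1), c(800, 800)),
               "outside")
})

test_that("small dense requests fail loudly rather than relaxing d_min", {
  # 60 points with 9 um exclusion in a 60x60 window cannot pack
  expect_error(
    generate_point_pattern("csr", 60, window = c(60, 60), d_min = 9,
                           max_attempts = 200, seed = 1),
    "packing|infeasible")
})

test_that("subtype assignment draws exact-count subsets by default", {
  p <- generate_point_pattern("csr", 200, seed = 11)
  p <- assign_subtypes(p, c(calr = 0.4, nnos = 0.3), seed = 12)
  expect_identical(sum(p$calr), 80L)
  expect_identical(sum(p$nnos), 60L)
  tr <- ground_truth(p)
  expect_identical(tr$subtypes$calr$n_positive, 80L)
  # Bernoulli mode varies around the nominal count
  q <- assign_subtypes(p, c(m = 0.5), exact = FALSE, seed = 13)
  expect_true(abs(sum(q$m) - 100) < 40)
  expect_error(assign_subtypes(p, c(0.4)), "named")
  expect_error(assign_subtypes(p, c(m = 1.4)), "0, 1")
})
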