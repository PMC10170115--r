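test_that("a two-point pattern fills exactly the two mirrored lag bins", {
  p <- as_ens_pattern(data.frame(x = c(100, 150), y = c(100, 100)),
                      c(800, 800))
  cif <- compute_cif(p, L = 200, bin = 4, smooth_sd = 0)
  expect_equal(sum(cif$raw), 2)
  ix_pos <- floor((50 + 200) / 4) + 1
  ix_neg <- floor((-50 + 200) / 4) + 1
  iy <- floor((0 + 200) / 4) + 1
  expect_equal(cif$raw[ix_pos, iy], 1)
  expect_equal(cif$raw[ix_neg, iy], 1)
})

test_that("raw CIF equals the brute-force pairwise histogram bin for bin", {
  for (s in 1:6) {
    n <- sample(20:150, 1)
    mode <- if (s %% 2 == 0) "csr" else "striped"
    p <- generate_point_pattern(mode, n, seed = s)
    cif <- compute_cif(p)
    expect_identical(unname(as.matrix(cif$raw)),
                     unname(cif_oracle(p$x, p$y, 200, 4)))
  }
})

test_that("raw and smoothed maps are symmetric under offset negation", {
  p <- generate_point_pattern("csr", 200, seed = 9)
  cif <- compute_cif(p)
  flip <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  expect_identical(cif$raw, flip(cif$raw))
  expect_equal(cif$smoothed, flip(cif$smoothed), tolerance = 1e-10)
})

test_that("raw counts are invariant to translating the whole pattern", {
  p <- generate_point_pattern("csr", 150, margin = 60, seed = 10)
  q <- as_ens_pattern(data.frame(x = p$x + 30, y = p$y - 25),
                      attr(p, "window"))
  expect_identical(compute_cif(p)$raw, compute_cif(q)$raw)
})

test_that("border and translation corrections agree on interior structure", {
  p <- generate_point_pattern("striped", 400, seed = 11)
  a <- compute_cif(p, L = 100, edge_correction = "translation")
  b <- compute_cif(p, L = 100, edge_correction = "border")
  # both corrections must expose the same stripe signal
  pa <- stripe_periodicity(a)
  pb <- stripe_periodicity(b)
  expect_true(pa$significant && pb$significant)
  expect_lt(abs(pa$period - pb$period), 10)
})

test_that("the clustering statistic is scale-free and zero for flat maps", {
  p <- generate_point_pattern("csr", 100, seed = 12)
  cif <- compute_cif(p)
  s1 <- clustering_statistic(cif)
  cif2 <- cif
  cif2$smoothed <- cif$smoothed * 2
  expect_equal(clustering_statistic(cif2), s1)
  flat <- cif
  flat$smoothed <- matrix(1, nrow(cif$raw), ncol(cif$raw))
  expect_equal(clustering_statistic(flat), 0)
  zero <- cif
  zero$smoothed <- matrix(0, nrow(cif$raw), ncol(cif$raw))
  expect_error(clustering_statistic(zero), "zero mean")
})

test_that("striped patterns score far above CSR patterns", {
  ps <- generate_point_pattern("striped", 300, seed = 13)
  pc <- generate_point_pattern("csr", 300, seed = 13)
  expect_gt(clustering_statistic(compute_cif(ps)),
            3 * clustering_statistic(compute_cif(pc)))
})

test_that("degenerate inputs are rejected with clear messages", {
  p1 <- as_ens_pattern(data.frame(x = 1, y = 1), c(800, 800))
  expect_error(compute_cif(p1), "at least 2")
  p <- generate_point_pattern("csr", 10, seed = 1)
  expect_error(compute_cif(p, L = 100, bin = 150), "exceed")
  expect_error(compute_cif(p, L = 100, bin = 7), "integer")
})
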