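#' Null ensemble of the clustering statistic under hard-core CSR
#'
#' Simulates `n_sim` pseudorandom patterns matched to the data — same point
#' count and window, complete spatial randomness with a hard-core minimum
#' distance (5 micrometres by default, since somata do not overlap) — and
#' evaluates the clustering statistic of each through the same CIF settings
#' as the data. One master seed spawns an independent substream per
#' replicate, so any single replicate is reproducible in isolation.
#'
#' @param n Number of points per null pattern.
#' @param window `c(width, height)` in micrometres.
#' @param d_min Hard-core distance (default 5).
#' @param n_sim Number of null samples (default 500).
#' @param L,bin,smooth_sd,normalize,edge_correction CIF settings; see
#'   [compute_cif()].
#' @param seed Master seed (integer).
#' @return Numeric vector of `n_sim` null statistic values; per-replicate
#'   substream seeds in the `"seeds"` attribute.
#' @export
simulate_null <- function(n, window = c(800, 800), d_min = 5, n_sim = 500,
                          L = 200, bin = 4, smooth_sd = 20, normalize = TRUE,
                          edge_correction = "translation", seed = NULL) {
  if (n_sim < 2L) abort("`n_sim` must be at least 2")
  if (n * pi * (d_min / 2)^2 >= 0.5 * prod(window))
    abort("infeasible packing for the null ensemble")
  seeds <- if (is.null(seed)) sample.int(2147483646L, n_sim) else
    derive_seeds(seed, n_sim)
  vals <- vapply(seq_len(n_sim), function(k) {
    withr::with_seed(seeds[k], {
      xy <- hardcore_csr_cpp(n, window[1], window[2], d_min, 0, 10000L)
      pat <- as_ens_pattern(tibble(x = xy[, 1], y = xy[, 2]), window, d_min)
      clustering_statistic(compute_cif(pat, L = L, bin = bin,
                                       smooth_sd = smooth_sd,
                                       normalize = normalize,
                                       edge_correction = edge_correction))
    })
  }, numeric(1))
  attr(vals, "seeds") <- seeds
  vals
}

#' z-score difference against a hard-core CSR null
#'
#' Quantifies how far a soma pattern departs from spatial randomness. The
#' data's clustering statistic is reduced to a z-score against the mean and
#' SD of the null ensemble; each null sample receives its own z-score
#' leave-one-out against the remaining samples (scoring a sample against an
#' ensemble containing itself would bias the null z toward zero); and the
#' z-score difference is the data z minus the mean null z. The 2.5th-97.5th
#' percentile band of the null z-scores is reported as the random-value
#' range: a `z_diff` above the band indicates non-random, clustered
#' organization.
#'
#' @param pattern An `ens_pattern` with at least 2 points.
#' @inheritParams simulate_null
#' @return An `ens_zscore` object; see [tidy.ens_zscore()] and
#'   [glance.ens_zscore()].
#' @export
zscore_difference <- function(pattern, L = 200, bin = 4, smooth_sd = 20,
                              d_min = 5, n_sim = 500, normalize = TRUE,
                              edge_correction = "translation", seed = NULL) {
  n <- nrow(pattern)
  if (n < 2L) abort("insufficient data: need at least 2 points")
  cif <- compute_cif(pattern, L = L, bin = bin, smooth_sd = smooth_sd,
                     normalize = normalize, edge_correction = edge_correction)
  s_data <- clustering_statistic(cif)
  nulls <- simulate_null(n, pattern_window(pattern), d_min = d_min,
                         n_sim = n_sim, L = L, bin = bin,
                         smooth_sd = smooth_sd, normalize = normalize,
                         edge_correction = edge_correction, seed = seed)
  mu <- mean(nulls); sdev <- sd(nulls)
  if (!is.finite(sdev) || sdev <= 0)
    abort("degenerate null: the clustering statistic has zero spread")
  z_data <- (s_data - mu) / sdev
  null_z <- loo_z(nulls)
  band <- unname(quantile(null_z, c(0.025, 0.975)))
  structure(list(statistic = s_data, null_mean = mu, null_sd = sdev,
                 null_values = as.numeric(nulls),
                 z_data = z_data, null_z = null_z,
                 z_diff = z_data - mean(null_z), band = band,
                 n = n, n_sim = n_sim, d_min = d_min, seed = seed,
                 settings = list(L = L, bin = bin, smooth_sd = smooth_sd,
                                 normalize = normalize,
                                 edge_correction = edge_correction),
                 cif = cif),
            class = "ens_zscore")
}

# Leave-one-out z-score of each null value against the rest of the ensemble.
loo_z <- function(vals) {
  m <- length(vals)
  tot <- sum(vals); ss <- sum(vals^2)
  mu_k <- (tot - vals) / (m - 1)
  var_k <- (ss - vals^2 - (m - 1) * mu_k^2) / (m - 2)
  var_k[var_k < 0] <- 0
  (vals - mu_k) / sqrt(var_k)
}

#' @export
print.ens_zscore <- function(x, ...) {
  cat(sprintf(
    "<ens_zscore> n = %d, z_diff = %.3f (null band [%.3f, %.3f], %d samples, d_min %g μm)\n",
    x$n, x$z_diff, x$band[1], x$band[2], x$n_sim, x$d_min))
  invisible(x)
}

#' Tidy the null ensemble of a z-score result
#'
#' @param x An `ens_zscore`.
#' @param ... Unused.
#' @return Tibble with one row per null sample: `statistic`, `z`.
#' @export
tidy.ens_zscore <- function(x, ...) {
  tibble(sample = seq_len(x$n_sim),
         statistic = x$null_values,
         z = as.numeric(x$null_z))
}

#' One-row summary of a z-score result
#'
#' @param x An `ens_zscore`.
#' @param ... Unused.
#' @return Tibble: `statistic`, `z_data`, `z_diff`, `band_lo`, `band_hi`,
#'   `null_mean`, `null_sd`, `n`, `n_sim`, `outside_band`.
#' @export
glance.ens_zscore <- function(x, ...) {
  tibble(statistic = x$statistic, z_data = x$z_data, z_diff = x$z_diff,
         band_lo = x$band[1], band_hi = x$band[2],
         null_mean = x$null_mean, null_sd = x$null_sd,
         n = x$n, n_sim = x$n_sim,
         outside_band = x$z_diff < x$band[1] | x$z_diff > x$band[2])
}
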