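#' Point patterns of neuron somata
#'
#' An `ens_pattern` is a tibble of soma coordinates with the observation
#' window and generation metadata attached as attributes. Coordinates are in
#' micrometres, continuous and 0-based, inside the half-open window
#' `[0, W) x [0, H)`. By convention `x` runs circumferentially and `y`
#' longitudinally, with the oral end at `y = 0`.
#'
#' @param points A data frame with numeric columns `x` and `y` (micrometres).
#'   Optional columns: `depth` (z position, micrometres) and logical subtype
#'   columns.
#' @param window Numeric pair `c(width, height)` in micrometres.
#' @param d_min Hard-core distance used at generation, if any (micrometres).
#' @param meta Named list of free-form metadata (region, age, seed, ...).
#' @param truth Optional ground-truth list attached by the generators.
#' @return A tibble of class `ens_pattern`.
#' @export
as_ens_pattern <- function(points, window, d_min = NA_real_, meta = list(),
                           truth = NULL) {
  points <- as_tibble(points)
  if (!all(c("x", "y") %in% names(points)))
    abort("`points` must have columns `x` and `y`")
  if (length(window) != 2L || any(!is.finite(window)) || any(window <= 0))
    abort("`window` must be two positive numbers (width, height) in μm")
  if (nrow(points) > 0) {
    inside <- points$x >= 0 & points$x < window[1] &
      points$y >= 0 & points$y < window[2]
    if (!all(inside))
      abort(sprintf("%d point(s) fall outside the window", sum(!inside)))
  }
  structure(points,
            class = c("ens_pattern", class(tibble())),
            window = as.numeric(window), d_min = d_min,
            meta = meta, truth = truth)
}

#' @export
print.ens_pattern <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("<ens_pattern> %d points in [0, %g) x [0, %g) μm\n",
              nrow(x), w[1], w[2]))
  NextMethod()
}

pattern_window <- function(pattern) {
  w <- attr(pattern, "window")
  if (is.null(w)) abort("pattern has no `window` attribute; use as_ens_pattern()")
  w
}

#' Ground truth attached to a synthetic object
#'
#' @param x An object produced by one of the generators.
#' @return The ground-truth list, or `NULL` for observed data.
#' @export
ground_truth <- function(x) attr(x, "truth", exact = TRUE)

#' Generate a synthetic soma point pattern
#'
#' Draws a seeded point pattern emulating myenteric-plexus wholemount fields:
#' hard-core complete spatial randomness (`"csr"`), somata concentrated in
#' circumferentially oriented stripes periodic along the gut axis
#' (`"striped"`), or stripes plus a set of "bridging" somata in the
#' inter-stripe gaps placed at a deeper z position (`"grid"`). All modes
#' enforce a minimum pairwise separation `d_min` (somata do not overlap in
#' space) by dart throwing with rejection; a point that cannot be placed
#' within `max_attempts` proposals raises a packing error rather than
#' silently relaxing `d_min`.
#'
#' @param mode `"csr"`, `"striped"` or `"grid"`.
#' @param n Number of points.
#' @param window `c(width, height)` in micrometres. Default 800 x 800, the
#'   field size of the wholemount maximum-intensity projections.
#' @param d_min Hard-core distance in micrometres (default 5).
#' @param stripe_period Stripe repeat distance along the periodic axis
#'   (micrometres).
#' @param stripe_width Width of each stripe band (micrometres).
#' @param p_in Probability that a stripe-class point falls inside a band.
#' @param stripe_phase Offset of the first band edge (micrometres).
#' @param orientation `"circumferential"` (bands periodic along `y`, the
#'   biological arrangement) or `"longitudinal"` (periodic along `x`, for
#'   robustness checks).
#' @param bridge_frac For `"grid"`: fraction of points in the bridging class.
#' @param depth_stripe,depth_bridge z positions (micrometres) given to
#'   stripe-class and bridge-class somata; stripe somata sit nearer the
#'   circular muscle, bridging somata nearer the longitudinal muscle.
#' @param margin Inset from the window edge within which points are placed
#'   (micrometres); useful when the pattern will be rendered and segmented so
#'   somata are not clipped by the field border.
#' @param max_attempts Dart-throwing cap per point.
#' @param seed Integer seed; identical arguments and seed give identical
#'   patterns.
#' @return An [as_ens_pattern()] tibble with columns `x`, `y`, `depth`,
#'   `class`, and ground truth retrievable with [ground_truth()].
#' @examples
#' p <- generate_point_pattern("striped", n = 150, seed = 1)
#' ground_truth(p)$stripe$period
#' @export
generate_point_pattern <- function(mode = c("csr", "striped", "grid"),
                                   n,
                                   window = c(800, 800),
                                   d_min = 5,
                                   stripe_period = 150,
                                   stripe_width = 40,
                                   p_in = 0.9,
                                   stripe_phase = 0,
                                   orientation = c("circumferential", "longitudinal"),
                                   bridge_frac = 0.25,
                                   depth_stripe = 3,
                                   depth_bridge = 15,
                                   margin = 0,
                                   max_attempts = 10000L,
                                   seed = NULL) {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    abort("`n` must be a single non-negative integer")
  n <- as.integer(n)
  window <- as.numeric(window)
  if (n * pi * (d_min / 2)^2 >= 0.5 * prod(window))
    abort("infeasible packing: requested points would exceed half the window area")

  if (n == 0L) {
    pts <- tibble(x = numeric(0), y = numeric(0), depth = numeric(0),
                  class = character(0))
    return(as_ens_pattern(pts, window, d_min,
                          meta = list(mode = mode, seed = seed),
                          truth = list(mode = mode, n = 0L, seed = seed)))
  }

  with_seed_if(seed, {
    if (mode == "csr") {
      xy <- hardcore_csr_cpp(n, window[1], window[2], d_min, margin,
                             as.integer(max_attempts))
      pts <- tibble(x = xy[, 1], y = xy[, 2],
                    depth = rep(depth_stripe, n), class = rep("stripe", n))
    } else {
      n_bridge <- if (mode == "grid") as.integer(round(bridge_frac * n)) else 0L
      classes <- rep(c("stripe", "bridge"), c(n - n_bridge, n_bridge))
      pts <- sample_striped_hardcore(
        n, classes, window, d_min, stripe_period, stripe_width, p_in,
        stripe_phase, orientation, margin, max_attempts)
      pts$depth <- ifelse(pts$class == "bridge", depth_bridge, depth_stripe)
    }
    truth <- list(
      mode = mode, n = n, seed = seed, d_min = d_min, margin = margin,
      stripe = if (mode != "csr")
        list(period = stripe_period, width = stripe_width, p_in = p_in,
             phase = stripe_phase, orientation = orientation),
      classes = pts$class, depths = pts$depth)
    as_ens_pattern(pts[c("x", "y", "depth", "class")], window, d_min,
                   meta = list(mode = mode, seed = seed), truth = truth)
  })
}

# In-band test for the periodic stripe geometry.
in_stripe_band <- function(coord, period, width, phase = 0) {
  ((coord - phase) %% period) < width
}

# Sequential dart throwing for stripe/grid modes. Stripe-class points draw
# their periodic coordinate from the band mixture (inside a band with
# probability p_in); bridge-class points use the complementary mixture so
# they fall preferentially between stripes.
sample_striped_hardcore <- function(n, classes, window, d_min, period, width,
                                    p_in, phase, orientation, margin,
                                    max_attempts) {
  if (width >= period) abort("`stripe_width` must be smaller than `stripe_period`")
  per_axis <- if (orientation == "circumferential") 2L else 1L  # periodic axis
  lim <- window[per_axis]
  x <- numeric(n); y <- numeric(n)
  d2 <- d_min^2
  for (k in seq_len(n)) {
    target_in <- if (classes[k] == "stripe") p_in else 1 - p_in
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      u <- runif(2)
      want_band <- runif(1) < target_in
      pc <- sample_periodic_coord(want_band, lim, period, width, phase, margin)
      oc <- margin + u[1] * (window[3L - per_axis] - 2 * margin)
      px <- if (per_axis == 1L) pc else oc
      py <- if (per_axis == 1L) oc else pc
      if (k == 1L || min((x[1:(k - 1)] - px)^2 + (y[1:(k - 1)] - py)^2) >= d2) {
        x[k] <- px; y[k] <- py; placed <- TRUE
        break
      }
    }
    if (!placed)
      abort(sprintf("hard-core packing failed at point %d of %d", k, n))
  }
  tibble(x = x, y = y, class = classes)
}

# Uniform draw along the periodic axis restricted to the band union or its
# complement, by rejection from the allowed interval.
sample_periodic_coord <- function(in_band, lim, period, width, phase, margin) {
  for (i in 1:10000) {
    v <- margin + runif(1) * (lim - 2 * margin)
    if (in_stripe_band(v, period, width, phase) == in_band) return(v)
  }
  abort("could not draw a coordinate in the requested stripe region")
}

#' Minimum pairwise distance of a point pattern
#'
#' Exhaustive check used to verify the hard-core property.
#'
#' @param pattern An `ens_pattern` or data frame with `x`, `y`.
#' @return Smallest pairwise distance in micrometres (`Inf` if fewer than 2
#'   points).
#' @export
min_pair_distance <- function(pattern) {
  min_pair_dist_cpp(pattern$x, pattern$y)
}

#' Assign subtype labels to a pattern
#'
#' Adds one logical column per marker. With `exact = TRUE` (the default) each
#' marker labels a uniformly chosen subset of exactly `round(fraction * n)`
#' somata, so the realized fraction matches the nominal one; with
#' `exact = FALSE` each soma is labelled independently with the given
#' probability.
#'
#' @param pattern An `ens_pattern`.
#' @param fractions Named numeric vector of marker fractions in `[0, 1]`,
#'   e.g. `c(calr = 0.4, nnos = 0.3)`.
#' @param exact Draw fixed-size subsets rather than independent Bernoulli
#'   labels.
#' @param seed Optional integer seed.
#' @return The pattern with added label columns; ground truth gains the
#'   per-marker probabilities and draws.
#' @export
assign_subtypes <- function(pattern, fractions, exact = TRUE, seed = NULL) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    abort("`fractions` must be a named numeric vector")
  if (any(fractions < 0 | fractions > 1))
    abort("subtype fractions must lie in [0, 1]")
  n <- nrow(pattern)
  truth <- attr(pattern, "truth") %||% list()
  with_seed_if(seed, {
    for (m in names(fractions)) {
      p <- fractions[[m]]
      lab <- if (exact) {
        k <- as.integer(round(p * n))
        pos <- rep(FALSE, n)
        pos[sample.int(n, k)] <- TRUE
        pos
      } else {
        runif(n) < p
      }
      pattern[[m]] <- lab
      truth$subtypes[[m]] <- list(probability = p, positive = lab,
                                  n_positive = sum(lab), exact = exact)
    }
  })
  attr(pattern, "truth") <- truth
  pattern
}
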