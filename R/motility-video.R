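#' Generate a synthetic gut-motility video
#'
#' Builds an analytic tube-diameter field `D(x, t)` — a baseline diameter
#' minus superposed travelling Gaussian indentations — and renders it as a
#' sequence of grayscale frames showing a dark tube on a light background,
#' emulating ex vivo organ-bath recordings (default 3.75 frames/s, 10-minute
#' segments). Two event families are supported: myogenic "ripples",
#' bidirectional indentations spreading both ways from random initiation
#' points at regular intervals, optionally gated into active/quiescent
#' cycles; and "neurogenic" waves propagating in one direction (distal by
#' default) at fixed intervals. Setting `ttx = TRUE` emulates tetrodotoxin:
#' neurogenic waves are removed, quiescent gating is lifted, and the ripple
#' rate may be rescaled.
#'
#' @param length_mm Tube length in millimetres (default 30, a mid-range ex
#'   vivo segment).
#' @param duration_s Recording length in seconds (default 600).
#' @param frame_rate Frames per second (default 3.75).
#' @param baseline_diameter Resting tube diameter, micrometres (default
#'   2000).
#' @param ripples `NULL`, or a list: `rate_per_min` (default 6), `velocity`
#'   (μm/s, default 1500), `amplitude` (μm, default 400), `width` (Gaussian
#'   SD, μm, default 800), `jitter_s` (onset jitter, default 1).
#' @param neurogenic `NULL`, or a list: `interval_s` (default 60),
#'   `velocity` (default 1000), `amplitude` (default 600), `width`
#'   (default 1000), `direction` (`"distal"` or `"proximal"`); an explicit
#'   `onsets` vector (s) overrides the regular schedule.
#' @param quiescent `NULL`, or a list `cycle_s`, `active_frac`: ripples are
#'   only initiated during the active part of each cycle (neurogenic
#'   inhibition of the muscle); lifted under TTX.
#' @param ttx Apply the TTX condition.
#' @param ttx_ripple_factor Multiplier on the ripple rate under TTX
#'   (default 1).
#' @param pixel_size Micrometres per pixel of the rendered frames
#'   (default 80).
#' @param noise_sd Per-pixel Gaussian noise SD on the frames (default 0.02).
#' @param seed Integer seed.
#' @return An `ens_video`: list with `frames` (array `[row, col, frame]`),
#'   `pixel_size`, `frame_rate`, `condition`, and ground truth holding the
#'   analytic diameter field (`diameter`, frames x columns, μm), the event
#'   table, and all parameters.
#' @export
generate_motility_video <- function(length_mm = 30,
                                    duration_s = 600,
                                    frame_rate = 3.75,
                                    baseline_diameter = 2000,
                                    ripples = list(),
                                    neurogenic = NULL,
                                    quiescent = NULL,
                                    ttx = FALSE,
                                    ttx_ripple_factor = 1,
                                    pixel_size = 80,
                                    noise_sd = 0.02,
                                    seed = NULL) {
  length_um <- length_mm * 1000
  nx <- as.integer(round(length_um / pixel_size))
  nt <- as.integer(round(duration_s * frame_rate))
  xc <- (seq_len(nx) - 0.5) * pixel_size
  times <- (seq_len(nt) - 1) / frame_rate

  if (!is.null(ripples))
    ripples <- utils::modifyList(
      list(rate_per_min = 6, velocity = 1500, amplitude = 400, width = 800,
           jitter_s = 1), ripples)
  if (!is.null(neurogenic))
    neurogenic <- utils::modifyList(
      list(interval_s = 60, velocity = 1000, amplitude = 600, width = 1000,
           direction = "distal"), neurogenic)
  gate <- quiescent
  if (ttx) {
    neurogenic <- NULL
    gate <- NULL
    if (!is.null(ripples))
      ripples$rate_per_min <- ripples$rate_per_min * ttx_ripple_factor
  }

  with_seed_if(seed, {
    events <- build_events(ripples, neurogenic, gate, duration_s, length_um)
    D <- diameter_field(events, baseline_diameter, xc, times, length_um)
    if (min(D) <= 0)
      abort("occlusion: wave amplitudes meet or exceed the baseline diameter")
    frames <- render_tube_frames(D, baseline_diameter, pixel_size, noise_sd)
    truth <- list(diameter = D, events = events, x = xc, times = times,
                  baseline_diameter = baseline_diameter,
                  ripple_rate_per_min = if (is.null(ripples)) 0 else
                    ripples$rate_per_min,
                  ttx = ttx, quiescent = gate, params = list(
                    length_mm = length_mm, duration_s = duration_s,
                    frame_rate = frame_rate, ripples = ripples,
                    neurogenic = neurogenic, pixel_size = pixel_size,
                    noise_sd = noise_sd, seed = seed))
    structure(list(frames = frames, pixel_size = pixel_size,
                   frame_rate = frame_rate,
                   condition = if (ttx) "ttx" else "baseline"),
              class = "ens_video", truth = truth)
  })
}

#' @export
print.ens_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<ens_video> %d frames of %d x %d px at %g fps (%.1f s), %g μm/px, condition %s\n",
    d[3], d[1], d[2], x$frame_rate, d[3] / x$frame_rate, x$pixel_size,
    x$condition))
  invisible(x)
}

# Event table construction. Ripple onsets sit on a regular grid (interval =
# 60 / rate) with uniform jitter so counts per minute are controlled;
# origins are uniform along the tube. Neurogenic waves start at the
# appropriate end every interval_s.
build_events <- function(ripples, neurogenic, gate, duration_s, length_um) {
  ev <- list()
  if (!is.null(ripples) && ripples$rate_per_min > 0) {
    interval <- 60 / ripples$rate_per_min
    onsets <- seq(interval / 2, duration_s, by = interval)
    onsets <- onsets + runif(length(onsets), -1, 1) * ripples$jitter_s
    onsets <- onsets[onsets > 0 & onsets < duration_s]
    if (!is.null(gate)) {
      phase <- onsets %% gate$cycle_s
      onsets <- onsets[phase < gate$active_frac * gate$cycle_s]
    }
    if (length(onsets) > 0)
      ev[[length(ev) + 1L]] <- tibble(
        type = "ripple", onset = onsets,
        origin = runif(length(onsets), 0.2, 0.8) * length_um,
        direction = "bidirectional",
        velocity = ripples$velocity, amplitude = ripples$amplitude,
        width = ripples$width)
  }
  if (!is.null(neurogenic)) {
    onsets <- neurogenic$onsets %||%
      (if (neurogenic$interval_s / 2 <= duration_s)
        seq(neurogenic$interval_s / 2, duration_s, by = neurogenic$interval_s)
       else numeric(0))
    if (length(onsets) > 0)
      ev[[length(ev) + 1L]] <- tibble(
        type = "neurogenic", onset = onsets,
        origin = if (neurogenic$direction == "distal") 0 else length_um,
        direction = neurogenic$direction,
        velocity = neurogenic$velocity, amplitude = neurogenic$amplitude,
        width = neurogenic$width)
  }
  if (length(ev) == 0)
    return(tibble(type = character(0), onset = numeric(0),
                  origin = numeric(0), direction = character(0),
                  velocity = numeric(0), amplitude = numeric(0),
                  width = numeric(0)))
  dplyr::arrange(dplyr::bind_rows(ev), .data$onset)
}

# Analytic diameter field: baseline minus travelling Gaussian indentations.
# A branch is active from its onset until its centre has left the tube by
# three Gaussian widths.
diameter_field <- function(events, baseline, xc, times, length_um) {
  D <- matrix(baseline, length(times), length(xc))
  if (nrow(events) == 0) return(D)
  for (e in seq_len(nrow(events))) {
    dirs <- switch(events$direction[e],
                   bidirectional = c(1, -1),
                   distal = 1,
                   proximal = -1)
    for (s in dirs) {
      w <- events$width[e]; v <- events$velocity[e]
      dt_max <- if (s > 0) (length_um + 3 * w - events$origin[e]) / v
                else (events$origin[e] + 3 * w) / v
      active <- which(times >= events$onset[e] &
                        times <= events$onset[e] + dt_max)
      for (ti in active) {
        centre <- events$origin[e] + s * v * (times[ti] - events$onset[e])
        D[ti, ] <- D[ti, ] -
          events$amplitude[e] * exp(-(xc - centre)^2 / (2 * w^2))
      }
    }
  }
  D
}

# Dark tube (intensity ~0.1) on light background (~0.9), centred vertically.
render_tube_frames <- function(D, baseline, pixel_size, noise_sd) {
  ny <- as.integer(ceiling(baseline * 1.4 / pixel_size))
  cy <- ny * pixel_size / 2
  rowc <- (seq_len(ny) - 0.5) * pixel_size
  nt <- nrow(D); nx <- ncol(D)
  frames <- array(0, c(ny, nx, nt))
  for (ti in seq_len(nt)) {
    half <- D[ti, ] / 2
    inside <- abs(outer(rowc, rep(cy, nx), "-")) <= rep(half, each = ny)
    f <- matrix(0.9, ny, nx)
    f[inside] <- 0.1
    if (noise_sd > 0) f <- f + rnorm(length(f), sd = noise_sd)
    frames[, , ti] <- pmin(pmax(f, 0), 1)
  }
  frames
}

#' Preset motility scenarios for developmental stages
#'
#' Three stage presets mirroring the progression of ex vivo motility:
#' `"ripples_only"` (13-15 weeks: continuous bidirectional myogenic
#' ripples), `"intermittent"` (18 weeks: ripples gated into active and
#' quiescent periods by neurogenic inhibition), and `"distal"` (21-22
#' weeks: exclusively distally propagating neurogenic contractions with few
#' ripples). With `ttx = TRUE` the neurogenic components are removed:
#' gating is lifted (quiescent periods ablated) and, in the `"distal"`
#' stage, the suppressed ripple rate recovers (ripple frequency increases).
#'
#' @param stage One of `"ripples_only"`, `"intermittent"`, `"distal"`.
#' @param ttx Apply the TTX condition.
#' @param duration_s Recording length (default 600).
#' @param seed Integer seed.
#' @param ... Overrides passed to [generate_motility_video()].
#' @return An `ens_video`.
#' @export
motility_scenario <- function(stage = c("ripples_only", "intermittent",
                                        "distal"),
                              ttx = FALSE, duration_s = 600, seed = NULL,
                              ...) {
  stage <- match.arg(stage)
  args <- switch(stage,
    ripples_only = list(
      ripples = list(rate_per_min = 6)),
    intermittent = list(
      ripples = list(rate_per_min = 6),
      quiescent = list(cycle_s = 120, active_frac = 0.55)),
    distal = list(
      ripples = list(rate_per_min = 1.5),
      neurogenic = list(interval_s = 60, direction = "distal"),
      ttx_ripple_factor = 4))
  args <- utils::modifyList(args, list(duration_s = duration_s, ttx = ttx,
                                       seed = seed, ...))
  do.call(generate_motility_video, args)
}
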