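#' Detect and classify contraction events on an STM
#'
#' A contraction is a spatiotemporally connected region where the diameter
#' drops more than `depth_threshold` below the per-position baseline (the
#' column median). Components closer than ~2 bins/frames are merged by a
#' small morphological closing before labelling. For each event the
#' per-frame position of minimum diameter is tracked and a least-squares
#' line through it gives the propagation velocity; an event whose leading
#' edges move apart with opposite slopes from a common origin is one
#' bidirectional event with a velocity per branch.
#'
#' @param stm An `ens_stm`.
#' @param depth_threshold Diameter drop defining contraction, micrometres
#'   (default 100).
#' @param min_duration_s Minimum event duration (default 1 s).
#' @param v_min Minimum |slope| (μm/s) for a branch to count as propagating
#'   (default 100).
#' @return Tibble of events: `onset` (s), `origin` (μm), `direction`
#'   (`"distal"`, `"proximal"`, `"bidirectional"`), `velocity` (μm/s; mean
#'   of branches for bidirectional), `velocity_distal`,
#'   `velocity_proximal`, `amplitude` (max depth, μm), `duration` (s).
#' @export
detect_contractions <- function(stm, depth_threshold = 100,
                                min_duration_s = 1, v_min = 100) {
  D <- stm$diameter[, stm$valid, drop = FALSE]
  xs <- stm$x[stm$valid]
  base <- apply(D, 2, median)
  depth <- sweep(D, 2, base, "-") * -1
  mask <- depth > depth_threshold
  empty <- tibble(onset = numeric(0), origin = numeric(0),
                  direction = character(0), velocity = numeric(0),
                  velocity_distal = numeric(0),
                  velocity_proximal = numeric(0),
                  amplitude = numeric(0), duration = numeric(0))
  if (!any(mask)) return(empty)
  closed <- EBImage::closing(mask, EBImage::makeBrush(3, "box")) > 0
  labels <- as.matrix(EBImage::bwlabel(closed))
  labels[!mask] <- 0L
  dt <- 1 / stm$frame_rate
  min_frames <- max(2L, ceiling(min_duration_s * stm$frame_rate))
  out <- list()
  for (lb in seq_len(max(labels))) {
    idx <- which(labels == lb, arr.ind = TRUE)
    frames <- sort(unique(idx[, 1]))
    if (length(frames) < min_frames) next
    tt <- stm$times[frames]
    track <- numeric(length(frames))   # position of min diameter per frame
    lo <- numeric(length(frames)); hi <- numeric(length(frames))
    for (k in seq_along(frames)) {
      cols <- idx[idx[, 1] == frames[k], 2]
      track[k] <- xs[cols[which.max(depth[frames[k], cols])]]
      lo[k] <- xs[min(cols)]; hi[k] <- xs[max(cols)]
    }
    # Branch test on the early phase of the event (first ~3 s), dropping
    # frames where an edge has saturated at the end of the field, so a
    # bidirectional event is recognized even when one branch later leaves.
    early <- seq_len(min(length(frames), max(3L, ceiling(3 * stm$frame_rate))))
    in_lo <- early[lo[early] > xs[1] + stm$bin_size / 2]
    in_hi <- early[hi[early] < xs[length(xs)] - stm$bin_size / 2]
    s_lo <- if (length(in_lo) >= 3L) ls_slope(tt[in_lo], lo[in_lo]) else NA_real_
    s_hi <- if (length(in_hi) >= 3L) ls_slope(tt[in_hi], hi[in_hi]) else NA_real_
    s_tr <- ls_slope(tt, track)
    amp <- max(depth[cbind(idx[, 1], idx[, 2])])
    if (is.finite(s_lo) && is.finite(s_hi) &&
        s_lo < -v_min && s_hi > v_min) {
      out[[length(out) + 1L]] <- tibble(
        onset = tt[1], origin = (lo[1] + hi[1]) / 2,
        direction = "bidirectional",
        velocity = mean(c(-s_lo, s_hi)),
        velocity_distal = s_hi, velocity_proximal = -s_lo,
        amplitude = amp, duration = tt[length(tt)] - tt[1] + dt)
    } else {
      dirn <- if (is.finite(s_tr) && s_tr >= 0) "distal" else "proximal"
      out[[length(out) + 1L]] <- tibble(
        onset = tt[1], origin = track[1], direction = dirn,
        velocity = abs(s_tr),
        velocity_distal = if (dirn == "distal") abs(s_tr) else NA_real_,
        velocity_proximal = if (dirn == "proximal") abs(s_tr) else NA_real_,
        amplitude = amp, duration = tt[length(tt)] - tt[1] + dt)
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$onset)
}

ls_slope <- function(t, x) {
  if (length(t) < 2L || sd(t) == 0) return(NA_real_)
  sum((t - mean(t)) * (x - mean(x))) / sum((t - mean(t))^2)
}

#' Myogenic ripple frequency from an STM
#'
#' Counts contraction minima per 60-second window in the diameter trace at
#' several sampled positions: local maxima of contraction depth with
#' topographic prominence at least `prominence` are events. The mean over
#' windows and positions is returned in events per minute — the automated
#' analogue of counting ripples along a one-minute stretch of the map.
#'
#' @param stm An `ens_stm` lasting at least `window_s`.
#' @param window_s Window length in seconds (default 60).
#' @param positions Positions to sample (μm); default five evenly spaced
#'   interior positions.
#' @param prominence Minimum peak prominence in micrometres of diameter
#'   (default 50).
#' @param min_separation_s Peaks closer than this are one event — the
#'   higher wins (default 2 s; diameter quantization at the pixel scale can
#'   split one contraction minimum into twins a few frames apart).
#' @return Events per minute (scalar).
#' @export
ripple_frequency <- function(stm, window_s = 60, positions = NULL,
                             prominence = 50, min_separation_s = 2) {
  dur <- max(stm$times)
  if (dur < window_s) abort("recording is shorter than one analysis window")
  xs <- stm$x[stm$valid]
  D <- stm$diameter[, stm$valid, drop = FALSE]
  positions <- positions %||%
    quantile(xs, c(0.25, 0.375, 0.5, 0.625, 0.75), names = FALSE)
  cols <- vapply(positions, function(p) which.min(abs(xs - p)), integer(1))
  n_win <- floor(dur / window_s)
  frames_per <- floor(window_s * stm$frame_rate)
  rates <- c()
  min_sep <- max(1L, floor(min_separation_s * stm$frame_rate))
  for (cl in unique(cols)) {
    trace <- D[, cl]
    depth <- median(trace) - trace
    depth <- stats::filter(depth, rep(1 / 3, 3), sides = 2)
    depth[is.na(depth)] <- 0
    pk <- peak_positions(as.numeric(depth), prominence)
    pk <- enforce_separation(pk, as.numeric(depth)[pk], min_sep)
    for (w in seq_len(n_win)) {
      in_w <- pk > (w - 1) * frames_per & pk <= w * frames_per
      rates <- c(rates, sum(in_w) / (window_s / 60))
    }
  }
  mean(rates)
}

# Greedy non-maximum suppression: visit peaks by decreasing height, drop
# any peak within min_sep frames of an already kept one.
enforce_separation <- function(pk, heights, min_sep) {
  if (length(pk) < 2L) return(pk)
  ord <- order(heights, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(pk[i] - kept) >= min_sep)) kept <- c(kept, pk[i])
  }
  sort(kept)
}

# Local maxima with topographic prominence >= prom. Prominence of a peak is
# its height above the higher of the two saddles separating it from higher
# ground (or the series minimum at the ends).
peak_positions <- function(x, prom) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]; h <- x[i]
    left <- if (i > 1) x[1:(i - 1)] else numeric(0)
    right <- if (i < n) x[(i + 1):n] else numeric(0)
    hl <- higher_run_min(left, h, from_end = TRUE)
    hr <- higher_run_min(right, h, from_end = FALSE)
    keep[k] <- (h - max(hl, hr)) >= prom
  }
  cand[keep]
}

# Minimum of the series between the peak and the nearest strictly higher
# point (series min when no higher point exists).
higher_run_min <- function(v, h, from_end) {
  if (length(v) == 0) return(-Inf)
  if (from_end) v <- rev(v)
  higher <- which(v > h)
  seg <- if (length(higher) == 0) v else v[seq_len(higher[1] - 1)]
  if (length(seg) == 0) h else min(seg)
}

#' Summarize a motility recording
#'
#' Combines the detected events and the STM into the per-recording summary
#' used for staging: ripple frequency, quiescent-time fraction (time spent
#' in contraction-free intervals of at least `min_quiescent_s`), direction
#' asymmetry index `(distal - proximal) / (distal + proximal)` over
#' directional events, and a pattern label. The label is
#' `"distal_propagating"` when the asymmetry exceeds `asym_threshold` with
#' at least `min_events` directional events, else
#' `"intermittent_neurogenic"` when the quiescent fraction exceeds
#' `quiescent_threshold` with bidirectional events present, else
#' `"ripples_only"`.
#'
#' @param events Tibble from [detect_contractions()] on the same STM.
#' @param stm The `ens_stm`.
#' @param depth_threshold Contraction depth used for the quiescence mask
#'   (μm).
#' @param min_quiescent_s Minimum length of a contraction-free interval to
#'   count as quiescence (default 20 s, well above the ripple period).
#' @param asym_threshold,quiescent_threshold,min_events Classification
#'   thresholds (defaults 0.8, 0.2, 3).
#' @param prominence Passed to [ripple_frequency()].
#' @return One-row tibble: `ripple_freq`, `quiescent_fraction`, `asymmetry`,
#'   `n_events`, `n_distal`, `n_proximal`, `n_bidirectional`, `label`,
#'   `low_activity`.
#' @export
classify_pattern <- function(events, stm, depth_threshold = 100,
                             min_quiescent_s = 20, asym_threshold = 0.8,
                             quiescent_threshold = 0.2, min_events = 3,
                             prominence = 50) {
  nd <- sum(events$direction == "distal")
  np <- sum(events$direction == "proximal")
  nb <- sum(events$direction == "bidirectional")
  asym <- if (nd + np > 0) (nd - np) / (nd + np) else 0
  qf <- quiescent_fraction(stm, depth_threshold, min_quiescent_s)
  freq <- if (max(stm$times) >= 60)
    ripple_frequency(stm, prominence = prominence) else NA_real_
  label <- if (asym > asym_threshold && nd + np >= min_events) {
    "distal_propagating"
  } else if (qf > quiescent_threshold && nb > 0) {
    "intermittent_neurogenic"
  } else {
    "ripples_only"
  }
  tibble(ripple_freq = freq, quiescent_fraction = qf, asymmetry = asym,
         n_events = nrow(events), n_distal = nd, n_proximal = np,
         n_bidirectional = nb, label = label,
         low_activity = nrow(events) == 0)
}

# Fraction of the recording spent in contraction-free runs of at least
# min_quiescent_s.
quiescent_fraction <- function(stm, depth_threshold = 100,
                               min_quiescent_s = 20) {
  D <- stm$diameter[, stm$valid, drop = FALSE]
  base <- apply(D, 2, median)
  active <- apply(sweep(D, 2, base, "-") * -1 > depth_threshold, 1, any)
  runs <- rle(!active)
  qlen <- runs$lengths[runs$values]
  dt <- 1 / stm$frame_rate
  sum(qlen[qlen * dt >= min_quiescent_s]) * dt / (length(active) * dt)
}

#' Compare a baseline and a treated recording
#'
#' Pairs the summaries of two STMs sharing spatial calibration (typically
#' baseline vs tetrodotoxin) and reports the deltas used to judge a
#' neurogenic contribution: change in ripple frequency, change in
#' quiescent-time fraction, and the pattern-label transition.
#'
#' @param baseline,treated `ens_stm` objects with equal `bin_size`.
#' @param ... Passed to [detect_contractions()] and [classify_pattern()].
#' @return One-row tibble with `_baseline` / `_treated` summary columns,
#'   `ripple_freq_change`, `quiescent_change`, `label_from`, `label_to`.
#' @export
compare_conditions <- function(baseline, treated, ...) {
  if (abs(baseline$bin_size - treated$bin_size) > 1e-9)
    abort("STMs differ in spatial calibration")
  opts <- list(...)
  det <- function(stm) {
    ev <- do.call(detect_contractions,
                  c(list(stm), opts[names(opts) %in%
                                      names(formals(detect_contractions))]))
    do.call(classify_pattern,
            c(list(ev, stm), opts[names(opts) %in%
                                    names(formals(classify_pattern))[-(1:2)]]))
  }
  b <- det(baseline); t <- det(treated)
  dplyr::bind_cols(
    dplyr::rename_with(b, ~ paste0(.x, "_baseline")),
    dplyr::rename_with(t, ~ paste0(.x, "_treated")),
    tibble(ripple_freq_change = t$ripple_freq - b$ripple_freq,
           quiescent_change = t$quiescent_fraction - b$quiescent_fraction,
           label_from = b$label, label_to = t$label))
}
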