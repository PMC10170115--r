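#' Spatiotemporal map (STM) of tube diameter
#'
#' Reduces a video of a contracting tube to a kymograph: per frame and per
#' longitudinal position (image column), the diameter is the vertical extent
#' of the dark tube silhouette after thresholding — extent (outermost minus
#' innermost foreground row), not pixel count, so lumen holes do not bias
#' the measurement. Columns lacking foreground in any frame are flagged
#' invalid; more than 20% invalid columns raises a quality error.
#'
#' @param video An `ens_video` or a frame array `[row, col, frame]`.
#' @param pixel_size,frame_rate Calibration; taken from an `ens_video`.
#' @param threshold Intensity below which a pixel is tube (default 0.5).
#' @param condition Condition tag: `"baseline"`, `"ttx"` or `"washout"`.
#' @return An `ens_stm`: list with `diameter` (frames x positions, μm),
#'   `times` (s), `x` (position bin centres, μm), `valid` (per-column mask),
#'   `frame_rate`, `bin_size`, `condition`.
#' @export
compute_stm <- function(video, pixel_size = NULL, frame_rate = NULL,
                        threshold = 0.5, condition = NULL) {
  if (inherits(video, "ens_video")) {
    frames <- video$frames
    pixel_size <- pixel_size %||% video$pixel_size
    frame_rate <- frame_rate %||% video$frame_rate
    condition <- condition %||% video$condition
  } else {
    frames <- video
    if (is.null(pixel_size) || is.null(frame_rate))
      abort("`pixel_size` and `frame_rate` are required for a plain frame array")
  }
  condition <- condition %||% "baseline"
  d <- dim(frames)
  if (length(d) != 3L) abort("frames must be a [row, col, frame] array")
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  rowidx <- matrix(seq_len(ny), ny, nx)
  revidx <- matrix(rev(seq_len(ny)), ny, nx)
  D <- matrix(NA_real_, nt, nx)
  bad <- matrix(FALSE, nt, nx)
  for (ti in seq_len(nt)) {
    mask <- frames[, , ti] < threshold
    a <- rowidx * mask
    b <- revidx * mask
    # column-wise max via row-wise max.col on the transpose
    ta <- t(a); tb <- t(b)
    rmax <- ta[cbind(seq_len(nx), max.col(ta, ties.method = "first"))]
    rminr <- tb[cbind(seq_len(nx), max.col(tb, ties.method = "first"))]
    none <- rmax == 0
    ext <- (rmax - (ny + 1L - rminr) + 1L) * pixel_size
    ext[none] <- NA_real_
    bad[ti, none] <- TRUE
    D[ti, ] <- ext
  }
  valid <- !apply(bad, 2, any)
  if (mean(valid) < 0.8) {
    abort(sprintf(
      "STM quality failure: %d of %d columns have frames with no tube foreground",
      sum(!valid), nx))
  }
  structure(list(diameter = D, times = (seq_len(nt) - 1) / frame_rate,
                 x = (seq_len(nx) - 0.5) * pixel_size, valid = valid,
                 frame_rate = frame_rate, bin_size = pixel_size,
                 condition = condition),
            class = "ens_stm")
}

#' @export
print.ens_stm <- function(x, ...) {
  cat(sprintf(
    "<ens_stm> %d frames x %d positions (%.1f s, %.1f mm), bin %g μm, condition %s\n",
    nrow(x$diameter), ncol(x$diameter), max(x$times),
    max(x$x) / 1000, x$bin_size, x$condition))
  invisible(x)
}

#' Long-format STM
#'
#' @param x An `ens_stm`.
#' @param ... Unused.
#' @return Tibble with `time`, `position`, `diameter`.
#' @export
tidy.ens_stm <- function(x, ...) {
  tibble(time = rep(x$times, times = ncol(x$diameter)),
         position = rep(x$x, each = nrow(x$diameter)),
         diameter = as.vector(x$diameter))
}
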