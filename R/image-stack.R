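#' Multi-channel fluorescence image stacks
#'
#' An `image_stack` holds one 3D intensity array per channel, indexed
#' `[row, col, slice]`, where row maps to `y`, column to `x`, and slice to
#' depth. Pixel `(r, c)` is centred at `((c - 0.5) * pixel_size,
#' (r - 0.5) * pixel_size)` micrometres, matching the 0-based continuous
#' coordinate convention of [as_ens_pattern()].
#'
#' @param channels Named list of non-negative 3D arrays (or 2D matrices,
#'   promoted to one slice) of identical dimensions.
#' @param pixel_size Lateral pixel size, micrometres per pixel.
#' @param z_step Axial slice spacing in micrometres (default 3, the stack
#'   interval used during acquisition).
#' @param truth Optional ground-truth list.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size, z_step = 3, truth = NULL) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  stopifnot_scalar_pos(z_step, "z_step")
  if (!is.list(channels) || is.null(names(channels)))
    abort("`channels` must be a named list of arrays")
  channels <- lapply(channels, function(a) {
    if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
    if (length(dim(a)) != 3L) abort("each channel must be a 2D or 3D array")
    a
  })
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L)
    abort("all channels must share the same dimensions")
  if (any(vapply(channels, function(a) any(a < 0), logical(1))))
    abort("intensities must be non-negative")
  structure(list(channels = channels, pixel_size = pixel_size,
                 z_step = z_step),
            class = "image_stack", truth = truth)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<image_stack> %d channel(s) [%s], %d x %d px x %d slice(s), %.3g μm/px, z-step %g μm\n",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    d[1], d[2], d[3], x$pixel_size, x$z_step))
  invisible(x)
}

get_channel <- function(stack, channel) {
  if (is.numeric(channel)) return(stack$channels[[channel]])
  if (!channel %in% names(stack$channels))
    abort(sprintf("no channel named '%s'", channel))
  stack$channels[[channel]]
}

#' Maximum-intensity projection of one channel
#'
#' @param stack An [image_stack()] (a plain matrix passes through).
#' @param channel Channel name or index.
#' @return A matrix `[row, col]`.
#' @export
max_project <- function(stack, channel = 1L) {
  if (is.matrix(stack)) return(stack)
  a <- get_channel(stack, channel)
  out <- a[, , 1L]
  nz <- dim(a)[3]
  if (nz > 1L) for (k in 2:nz) out <- pmax(out, a[, , k])
  out
}

# argmax slice index per pixel, ties to the first slice
argmax_slice <- function(a) {
  best <- a[, , 1L]
  arg <- matrix(1L, nrow(best), ncol(best))
  nz <- dim(a)[3]
  if (nz > 1L) for (k in 2:nz) {
    upd <- a[, , k] > best
    best[upd] <- a[, , k][upd]
    arg[upd] <- k
  }
  arg
}

# Paint filled disks into one slice of an accumulator array.
add_disks <- function(arr, slice, cx, cy, radius, pixel_size, intensity = 1) {
  ny <- dim(arr)[1]; nx <- dim(arr)[2]
  for (i in seq_along(cx)) {
    c0 <- max(1L, floor((cx[i] - radius) / pixel_size) + 1L)
    c1 <- min(nx, ceiling((cx[i] + radius) / pixel_size))
    r0 <- max(1L, floor((cy[i] - radius) / pixel_size) + 1L)
    r1 <- min(ny, ceiling((cy[i] + radius) / pixel_size))
    if (c0 > c1 || r0 > r1) next
    px <- (c0:c1 - 0.5) * pixel_size
    py <- (r0:r1 - 0.5) * pixel_size
    inside <- outer((py - cy[i])^2, (px - cx[i])^2, "+") <= radius^2
    blk <- arr[r0:r1, c0:c1, slice[i]]
    blk[inside] <- blk[inside] + intensity
    arr[r0:r1, c0:c1, slice[i]] <- blk
  }
  arr
}

# Additive Gaussian background plus per-pixel Poisson shot noise at a given
# photon scale (0 disables the Poisson component).
apply_noise <- function(arr, background = 0.05, gaussian_sd = 0.01,
                        poisson_scale = 200) {
  if (poisson_scale > 0) {
    arr[] <- rpois(length(arr), pmax(arr, 0) * poisson_scale) / poisson_scale
  }
  arr <- arr + background + rnorm(length(arr), sd = gaussian_sd)
  arr[arr < 0] <- 0
  arr
}

#' Render a wholemount z-stack from a point pattern
#'
#' Each soma is drawn as a filled disk of area `soma_area` in the z-slice
#' nearest its `depth`, optionally blurred laterally and degraded with mild
#' additive Gaussian background plus per-pixel Poisson noise. One channel per
#' logical subtype column of the pattern is rendered in addition to the
#' pan-neuronal reference channel, containing exactly the somata whose label
#' is positive.
#'
#' @param pattern An `ens_pattern`; any logical columns are treated as
#'   subtype labels.
#' @param soma_area Rendered soma area, square micrometres. Default 138, the
#'   per-neuron area unit used for area-based counting, so rendering and
#'   counting are mutually calibrated.
#' @param pixel_size Micrometres per pixel (default 1).
#' @param z_step Slice spacing in micrometres (default 3).
#' @param n_slices Number of slices; defaults to cover the deepest soma.
#' @param blur_sigma Lateral point-spread blur in micrometres (default 0.5).
#' @param noise List of `background`, `gaussian_sd`, `poisson_scale`; see
#'   Details. Use `NULL` for a noiseless render.
#' @param reference_name Name of the pan-neuronal channel (default "huc").
#' @param seed Optional integer seed for the noise.
#' @return An [image_stack()] whose ground truth records the pattern and all
#'   subtype draws.
#' @export
render_wholemount <- function(pattern,
                              soma_area = 138,
                              pixel_size = 1,
                              z_step = 3,
                              n_slices = NULL,
                              blur_sigma = 0.5,
                              noise = list(),
                              reference_name = "huc",
                              seed = NULL) {
  stopifnot_scalar_pos(soma_area, "soma_area")
  window <- pattern_window(pattern)
  if (pixel_size > 1)
    warn("pixel_size > 1 μm/px; round-trip segmentation may lose precision")
  radius <- sqrt(soma_area / pi)
  if (2 * radius / pixel_size < 2)
    abort("soma diameter is below 2 px at this pixel size; use a finer grid")
  nx <- as.integer(round(window[1] / pixel_size))
  ny <- as.integer(round(window[2] / pixel_size))
  depth <- if ("depth" %in% names(pattern)) pattern$depth else rep(0, nrow(pattern))
  slice <- pmax(1L, as.integer(round(depth / z_step)) + 1L)
  nz <- if (is.null(n_slices)) max(1L, slice) else as.integer(n_slices)
  if (any(slice > nz)) abort("`n_slices` too small for the deepest soma")

  label_cols <- names(pattern)[vapply(pattern, is.logical, logical(1))]
  with_seed_if(seed, {
    chans <- list()
    base <- array(0, c(ny, nx, nz))
    chans[[reference_name]] <-
      add_disks(base, slice, pattern$x, pattern$y, radius, pixel_size)
    for (m in label_cols) {
      pos <- pattern[[m]]
      chans[[m]] <- add_disks(base, slice[pos], pattern$x[pos],
                              pattern$y[pos], radius, pixel_size)
    }
    if (blur_sigma > 0) {
      sp <- blur_sigma / pixel_size
      chans <- lapply(chans, function(a) {
        for (k in seq_len(dim(a)[3]))
          a[, , k] <- EBImage::gblur(a[, , k], sigma = sp)
        a[a < 0] <- 0
        a
      })
    }
    if (!is.null(noise)) {
      noise <- utils::modifyList(
        list(background = 0.05, gaussian_sd = 0.01, poisson_scale = 200), noise)
      chans <- lapply(chans, function(a)
        apply_noise(a, noise$background, noise$gaussian_sd, noise$poisson_scale))
    }
    truth <- c(attr(pattern, "truth") %||% list(),
               list(pattern = pattern, soma_area = soma_area,
                    slice = slice, label_cols = label_cols))
    image_stack(chans, pixel_size, z_step, truth = truth)
  })
}
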