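#' Depth projection of a z-stack
#'
#' For every foreground pixel, the depth is the z-step times the (0-based)
#' index of the brightest slice — the quantitative analogue of a
#' pseudocoloured temporal/depth projection. Background pixels are `NA`.
#' The result is invariant to uniform intensity scaling of the stack.
#'
#' @param stack An [image_stack()].
#' @param channel Channel to project.
#' @param threshold Foreground rule applied to the maximum projection:
#'   `"otsu"` or a numeric cutoff on the 0-1 normalized projection.
#' @return Matrix of depths in micrometres (`NA` = background).
#' @export
depth_projection <- function(stack, channel = 1L, threshold = "otsu") {
  a <- get_channel(stack, channel)
  proj <- max_project(stack, channel)
  rng <- range(proj)
  if (diff(rng) <= 0)
    return(matrix(NA_real_, nrow(proj), ncol(proj)))
  img <- (proj - rng[1]) / diff(rng)
  thr <- if (identical(threshold, "otsu")) EBImage::otsu(img) else threshold
  fg <- img >= thr
  depth <- (argmax_slice(a) - 1L) * stack$z_step
  depth[!fg] <- NA_real_
  depth
}

#' Depth of each soma from a depth projection
#'
#' Reads the depth map at each soma position (median over the foreground
#' pixels of a small neighbourhood), e.g. to separate stripe somata near the
#' circular muscle from bridging somata near the longitudinal muscle.
#'
#' @param depth_map Matrix from [depth_projection()].
#' @param centroids Data frame with `x`, `y` in micrometres (a pattern or
#'   segmentation centroid table).
#' @param pixel_size Micrometres per pixel.
#' @param halfwidth Neighbourhood half-width in pixels (default 2).
#' @return Numeric vector of per-soma depths in micrometres (`NA` when no
#'   foreground pixel is found nearby).
#' @export
soma_depths <- function(depth_map, centroids, pixel_size, halfwidth = 2L) {
  ny <- nrow(depth_map); nx <- ncol(depth_map)
  vapply(seq_len(nrow(centroids)), function(i) {
    c0 <- as.integer(floor(centroids$x[i] / pixel_size)) + 1L
    r0 <- as.integer(floor(centroids$y[i] / pixel_size)) + 1L
    rr <- max(1L, r0 - halfwidth):min(ny, r0 + halfwidth)
    cc <- max(1L, c0 - halfwidth):min(nx, c0 + halfwidth)
    v <- depth_map[rr, cc]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else median(v)
  }, numeric(1))
}

#' Two-class depth assignment
#'
#' Splits somata into a shallow and a deep class at the midpoint between the
#' two stated class depths (or at the midpoint of the observed depth range).
#'
#' @param depths Per-soma depths from [soma_depths()].
#' @param class_depths Optional numeric pair of the two nominal depths.
#' @return Factor with levels `"shallow"` and `"deep"`.
#' @export
classify_depth <- function(depths, class_depths = NULL) {
  cut_at <- if (!is.null(class_depths)) mean(class_depths) else
    mean(range(depths, na.rm = TRUE))
  factor(ifelse(depths >= cut_at, "deep", "shallow"),
         levels = c("shallow", "deep"))
}
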