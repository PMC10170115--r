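#' Area-based neuron count
#'
#' Tightly packed somata cannot be resolved individually, so neuron number is
#' approximated as total labelled area divided by the area of one neuron.
#' The default unit of 138 square micrometres is the per-neuron area derived
#' from a mean soma diameter of 9.374 micrometres measured across fields.
#'
#' @param x An `ens_segmentation`, a binary mask matrix, or an
#'   [image_stack()]/intensity matrix (processed with `blur_sigma` and
#'   `threshold` first).
#' @param unit_area Area of one neuron in square micrometres (default 138).
#' @param pixel_size Micrometres per pixel; required for plain matrices.
#' @param channel,blur_sigma,threshold Used only when `x` is an image
#'   (default blur 1 μm: denoise below the edge scale so labelled area is
#'   preserved).
#' @return Estimated neuron count (real-valued).
#' @export
estimate_neuron_count_by_area <- function(x, unit_area = 138,
                                          pixel_size = NULL, channel = 1L,
                                          blur_sigma = 1, threshold = "otsu") {
  stopifnot_scalar_pos(unit_area, "unit_area")
  fg <- foreground_mask(x, pixel_size, channel, blur_sigma, threshold)
  sum(fg$mask) * fg$pixel_size^2 / unit_area
}

# Normalize the many accepted inputs to (binary mask, pixel size).
foreground_mask <- function(x, pixel_size = NULL, channel = 1L,
                            blur_sigma = 1, threshold = "otsu") {
  if (inherits(x, "ens_segmentation"))
    return(list(mask = x$labels > 0L, pixel_size = x$pixel_size))
  if (is.matrix(x) && is.logical(x)) {
    if (is.null(pixel_size)) abort("`pixel_size` is required for a plain mask")
    return(list(mask = x, pixel_size = pixel_size))
  }
  ps <- pixel_size %||% (if (inherits(x, "image_stack")) x$pixel_size else
    abort("`pixel_size` is required for a plain intensity matrix"))
  proj <- max_project(x, channel)
  rng <- range(proj)
  if (diff(rng) <= 0)
    return(list(mask = matrix(FALSE, nrow(proj), ncol(proj)), pixel_size = ps))
  img <- (proj - rng[1]) / diff(rng)
  if (blur_sigma > 0) img <- EBImage::gblur(img, sigma = blur_sigma / ps)
  thr <- if (identical(threshold, "otsu")) EBImage::otsu(img) else threshold
  list(mask = img >= thr, pixel_size = ps)
}

#' Count double-positive somata by colocalization
#'
#' Thresholds the reference and subtype channels, intersects the masks
#' (pixelwise AND of the maximum-intensity projections), and counts connected
#' components above `min_size`.
#'
#' @param reference,subtype [image_stack()]s or intensity matrices sharing
#'   shape and calibration.
#' @param min_size Minimum component area, square micrometres.
#' @param pixel_size Required for plain matrices.
#' @param reference_channel,subtype_channel Channel selectors when a
#'   multi-channel stack is passed.
#' @param blur_sigma,threshold Passed to the per-channel thresholding.
#' @return Integer count of double-positive somata.
#' @export
colocalize <- function(reference, subtype, min_size = 20, pixel_size = NULL,
                       reference_channel = 1L, subtype_channel = 1L,
                       blur_sigma = 1, threshold = "otsu") {
  a <- foreground_mask(reference, pixel_size, reference_channel, blur_sigma, threshold)
  b <- foreground_mask(subtype, pixel_size, subtype_channel, blur_sigma, threshold)
  if (!identical(dim(a$mask), dim(b$mask)))
    abort("reference and subtype images differ in shape")
  if (abs(a$pixel_size - b$pixel_size) > 1e-9)
    abort("reference and subtype images differ in calibration")
  both <- a$mask & b$mask
  if (!any(both)) return(0L)
  labels <- filter_min_size(as.matrix(EBImage::bwlabel(both)),
                            min_size / a$pixel_size^2)
  max(labels)
}

#' Subtype representation among neurons
#'
#' Fraction of neurons positive for a subtype marker: the double-positive
#' count divided by the area-based estimate of total neuron number,
#' optionally restricted to a polygonal region of interest (e.g. isolating
#' the myenteric plexus on a cross-section).
#'
#' @inheritParams colocalize
#' @param unit_area Per-neuron area for the denominator (default 138).
#' @param roi Optional region of interest: a two-column matrix of polygon
#'   vertices in micrometres, or `c(x, y, width, height)` for a rectangle.
#' @return One-row tibble: `total_estimate`, `double_positive`, `fraction`,
#'   `unit_area`, and `flag` (`"undefined"` when no neurons are found,
#'   `"gt1"` when over-segmentation pushes the fraction above 1).
#' @export
subtype_fraction <- function(reference, subtype, unit_area = 138,
                             min_size = 20, roi = NULL, pixel_size = NULL,
                             reference_channel = 1L, subtype_channel = 1L,
                             blur_sigma = 1, threshold = "otsu") {
  a <- foreground_mask(reference, pixel_size, reference_channel, blur_sigma, threshold)
  b <- foreground_mask(subtype, pixel_size, subtype_channel, blur_sigma, threshold)
  if (!identical(dim(a$mask), dim(b$mask)))
    abort("reference and subtype images differ in shape")
  if (!is.null(roi)) {
    keep <- roi_mask(dim(a$mask), a$pixel_size, roi)
    a$mask <- a$mask & keep
    b$mask <- b$mask & keep
  }
  total <- sum(a$mask) * a$pixel_size^2 / unit_area
  both <- a$mask & b$mask
  dp <- if (any(both)) {
    max(filter_min_size(as.matrix(EBImage::bwlabel(both)),
                        min_size / a$pixel_size^2))
  } else 0L
  frac <- if (total > 0) dp / total else NA_real_
  flag <- if (total <= 0) "undefined" else if (isTRUE(frac > 1)) "gt1" else NA_character_
  tibble(total_estimate = total, double_positive = as.integer(dp),
         fraction = frac, unit_area = unit_area, flag = flag)
}

# Logical mask of pixels whose centres fall inside a polygon (even-odd rule)
# or rectangle given in micrometres.
roi_mask <- function(dims, pixel_size, roi) {
  if (is.numeric(roi) && is.null(dim(roi)) && length(roi) == 4L) {
    roi <- cbind(x = roi[1] + c(0, roi[3], roi[3], 0),
                 y = roi[2] + c(0, 0, roi[4], roi[4]))
  }
  roi <- as.matrix(roi)
  if (ncol(roi) != 2L || nrow(roi) < 3L)
    abort("`roi` must be a polygon matrix (>= 3 vertices) or c(x, y, w, h)")
  xs <- (seq_len(dims[2]) - 0.5) * pixel_size
  ys <- (seq_len(dims[1]) - 0.5) * pixel_size
  if (max(roi[, 1]) > dims[2] * pixel_size || max(roi[, 2]) > dims[1] * pixel_size ||
      min(roi) < 0)
    abort("`roi` extends outside the image")
  inside <- matrix(FALSE, dims[1], dims[2])
  nv <- nrow(roi)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- roi[i, 1]; yi <- roi[i, 2]; xj <- roi[j, 1]; yj <- roi[j, 2]
    # ray casting along +x for every pixel row at once
    crosses_row <- (ys > pmin(yi, yj)) & (ys <= pmax(yi, yj))
    if (any(crosses_row) && yi != yj) {
      xint <- xi + (ys[crosses_row] - yi) / (yj - yi) * (xj - xi)
      flip <- outer(xint, xs, function(a, b) b < a)
      inside[crosses_row, ] <- xor(inside[crosses_row, , drop = FALSE], flip)
    }
    j <- i
  }
  inside
}
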