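#' Segment neuron somata from a wholemount channel
#'
#' Works on the maximum-intensity projection of a single channel: Gaussian
#' blur, threshold (Otsu by default), optional watershed splitting of
#' touching somata on the distance transform, size filtering, and
#' area-weighted centroid extraction in micrometres.
#'
#' @param stack An [image_stack()] or a plain intensity matrix.
#' @param channel Channel to segment (default the first).
#' @param blur_sigma Blur standard deviation in micrometres (default 2,
#'   below the soma scale).
#' @param threshold `"otsu"` or a numeric cutoff on the blurred, range-
#'   normalized image (0-1 scale).
#' @param min_size Minimum object area in square micrometres (default 20,
#'   rejects noise specks).
#' @param split_touching Split touching objects by watershed on the distance
#'   transform of the binary mask (default `TRUE`).
#' @param ws_tolerance Watershed tolerance: minimum distance-transform depth
#'   separating two catchment basins (default 0.5 px; deeply overlapping
#'   somata leave only a shallow saddle).
#' @param pixel_size Micrometres per pixel; taken from the stack when
#'   available.
#' @return An `ens_segmentation`: list with the integer label image
#'   (`labels`, 0 = background), a `centroids` tibble (`label`, `x`, `y`,
#'   `area`), the binary `mask`, processing parameters, and a `flag` set to
#'   `"empty"` when the image had no usable signal. `tidy()` returns the
#'   centroid table, [as_pattern()] converts it to an `ens_pattern`.
#' @export
segment_neurons <- function(stack, channel = 1L, blur_sigma = 2,
                            threshold = "otsu", min_size = 20,
                            split_touching = TRUE, ws_tolerance = 0.5,
                            pixel_size = NULL) {
  ps <- pixel_size %||% (if (inherits(stack, "image_stack")) stack$pixel_size else
    abort("`pixel_size` is required when `stack` is a plain matrix"))
  proj <- max_project(stack, channel)
  rng <- range(proj)
  params <- list(blur_sigma = blur_sigma, threshold = threshold,
                 min_size = min_size, split_touching = split_touching,
                 pixel_size = ps)
  if (diff(rng) <= 0) {
    warn("image is constant (empty or saturated); returning empty result")
    return(new_segmentation(matrix(0L, nrow(proj), ncol(proj)),
                            ps, params, flag = "empty"))
  }
  img <- (proj - rng[1]) / diff(rng)
  if (blur_sigma > 0) img <- EBImage::gblur(img, sigma = blur_sigma / ps)
  thr <- if (identical(threshold, "otsu")) EBImage::otsu(img) else threshold
  mask <- img >= thr
  if (!any(mask)) {
    warn("no foreground after thresholding; returning empty result")
    return(new_segmentation(matrix(0L, nrow(proj), ncol(proj)),
                            ps, params, flag = "empty"))
  }
  labels <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(mask), tolerance = ws_tolerance,
                       ext = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  labels <- filter_min_size(as.matrix(labels), min_size / ps^2)
  new_segmentation(labels, ps, params, mask = mask)
}

# Drop labels below min_px pixels and relabel 1..K contiguously.
filter_min_size <- function(labels, min_px) {
  if (max(labels) == 0L) return(labels)
  sizes <- tabulate(labels, nbins = max(labels))
  keep <- which(sizes >= min_px)
  remap <- integer(max(labels))
  remap[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0L] <- remap[labels[labels > 0L]]
  out
}

new_segmentation <- function(labels, pixel_size, params, mask = NULL,
                             flag = NA_character_) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  k <- max(labels, 0L)
  cent <- if (k > 0L) {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    rc <- arrayInd(idx, dim(labels))
    npx <- tabulate(lab, nbins = k)
    # area-weighted (binary) centroids of pixel centres, 0-based μm
    sy <- rowsum(rc[, 1] - 0.5, lab)[, 1]
    sx <- rowsum(rc[, 2] - 0.5, lab)[, 1]
    tibble(label = seq_len(k),
           x = sx / npx * pixel_size,
           y = sy / npx * pixel_size,
           area = npx * pixel_size^2)
  } else {
    tibble(label = integer(0), x = numeric(0), y = numeric(0),
           area = numeric(0))
  }
  structure(list(labels = labels, centroids = cent,
                 mask = mask %||% (labels > 0L),
                 pixel_size = pixel_size, params = params, flag = flag),
            class = "ens_segmentation")
}

#' @export
print.ens_segmentation <- function(x, ...) {
  cat(sprintf("<ens_segmentation> %d object(s), %.3g μm/px%s\n",
              nrow(x$centroids), x$pixel_size,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' @export
tidy.ens_segmentation <- function(x, ...) x$centroids

#' Convert a segmentation to a point pattern
#'
#' @param seg An `ens_segmentation`.
#' @return An `ens_pattern` of the detected centroids with the image extent
#'   as window.
#' @export
as_pattern <- function(seg) {
  d <- dim(seg$labels)
  as_ens_pattern(seg$centroids[c("x", "y")],
                 window = c(d[2], d[1]) * seg$pixel_size,
                 meta = list(source = "segmentation"))
}
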