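#' Render a synthetic intestinal cross-section
#'
#' Builds a multi-channel 2D image of horizontal tissue bands stacked from
#' the lumen outward — mucosa, submucosal plexus (SMP), circular muscle
#' (CM), myenteric plexus (MP), longitudinal muscle (LM) — with scattered
#' nuclei and neuron somata in the MP band. Channels: `sma` (smooth muscle,
#' CM + LM bands), `sox10` (MP nuclei at the stated density), `huc` (neuron
#' somata), and `caspase` (an "apoptotic" channel marking a stated fraction
#' of the neurons).
#'
#' @param layers Named numeric vector of band thicknesses in micrometres, in
#'   order `mucosa`, `smp`, `cm`, `mp`, `lm`.
#' @param width Image width (tissue extent) in micrometres.
#' @param nucleus_density MP nuclei per square micrometre; the rendered count
#'   is a Poisson draw and the exact value is stored in the ground truth.
#' @param n_neurons Number of neuron somata placed in the MP band (hard-core
#'   `neuron_d_min`).
#' @param apoptotic_fraction Fraction of neurons marked in the `caspase`
#'   channel (exact-count draw).
#' @param soma_area Neuron soma area, square micrometres.
#' @param nucleus_radius Nucleus radius in micrometres.
#' @param neuron_d_min Hard-core distance between neuron centres.
#' @param pixel_size Micrometres per pixel.
#' @param noise As in [render_wholemount()]; `NULL` disables.
#' @param seed Optional integer seed.
#' @return An [image_stack()] (single slice per channel) whose ground truth
#'   records layer geometry, nucleus and neuron positions, and apoptotic
#'   draws.
#' @export
render_cross_section <- function(layers = c(mucosa = 150, smp = 30, cm = 30,
                                            mp = 40, lm = 25),
                                 width = 800,
                                 nucleus_density = 5e-4,
                                 n_neurons = 50,
                                 apoptotic_fraction = 0,
                                 soma_area = 138,
                                 nucleus_radius = 3,
                                 neuron_d_min = 10,
                                 pixel_size = 1,
                                 noise = list(),
                                 seed = NULL) {
  need <- c("mucosa", "smp", "cm", "mp", "lm")
  if (!all(need %in% names(layers)))
    abort("`layers` must name thicknesses for mucosa, smp, cm, mp, lm")
  layers <- layers[need]
  if (any(layers <= 0)) abort("layer thicknesses must be positive")
  height <- sum(layers)
  ny <- as.integer(round(height / pixel_size))
  nx <- as.integer(round(width / pixel_size))
  if (ny < length(layers)) abort("bands exceed the image height at this pixel size")
  tops <- cumsum(c(0, layers[-length(layers)]))
  names(tops) <- need
  band_rows <- function(layer) {
    r0 <- floor(tops[[layer]] / pixel_size) + 1L
    r1 <- floor((tops[[layer]] + layers[[layer]]) / pixel_size)
    r0:min(r1, ny)
  }

  with_seed_if(seed, {
    sma <- matrix(0, ny, nx)
    sma[band_rows("cm"), ] <- 1
    sma[band_rows("lm"), ] <- 1

    mp_top <- tops[["mp"]]; mp_h <- layers[["mp"]]
    mp_area <- mp_h * width
    n_nuc <- rpois(1, nucleus_density * mp_area)
    # count is the Poisson draw; placement keeps a small exclusion so every
    # instance stays resolvable as its own connected component
    nuc <- place_in_band(n_nuc, width, mp_top, mp_h,
                         d_min = 2.2 * nucleus_radius,
                         margin_x = nucleus_radius, pad = nucleus_radius)
    nuc_x <- nuc$x
    nuc_y <- nuc$y
    sox10 <- array(0, c(ny, nx, 1L))
    sox10 <- add_disks(sox10, rep(1L, n_nuc), nuc_x, nuc_y,
                       nucleus_radius, pixel_size)[, , 1]

    soma_r <- sqrt(soma_area / pi)
    neu <- place_in_band(n_neurons, width, mp_top, mp_h, neuron_d_min,
                         margin_x = soma_r, pad = soma_r)
    huc <- array(0, c(ny, nx, 1L))
    huc <- add_disks(huc, rep(1L, n_neurons), neu$x, neu$y, soma_r,
                     pixel_size)[, , 1]
    n_apo <- as.integer(round(apoptotic_fraction * n_neurons))
    apo <- rep(FALSE, n_neurons)
    if (n_apo > 0) apo[sample.int(n_neurons, n_apo)] <- TRUE
    caspase <- array(0, c(ny, nx, 1L))
    caspase <- add_disks(caspase, rep(1L, sum(apo)), neu$x[apo], neu$y[apo],
                         soma_r, pixel_size)[, , 1]

    chans <- list(sma = sma, sox10 = sox10, huc = huc, caspase = caspase)
    if (!is.null(noise)) {
      noise <- utils::modifyList(
        list(background = 0.05, gaussian_sd = 0.01, poisson_scale = 200), noise)
      chans <- lapply(chans, function(m)
        apply_noise(m, noise$background, noise$gaussian_sd, noise$poisson_scale))
    }
    truth <- list(layers = layers, tops = tops, width = width,
                  nucleus_density = nucleus_density, n_nuclei = n_nuc,
                  nuclei = tibble(x = nuc_x, y = nuc_y),
                  neurons = tibble(x = neu$x, y = neu$y, apoptotic = apo),
                  n_neurons = n_neurons, apoptotic_fraction = apoptotic_fraction,
                  n_apoptotic = n_apo, soma_area = soma_area,
                  mp_roi = c(0, mp_top, width, mp_h))
    image_stack(chans, pixel_size, z_step = 3, truth = truth)
  })
}

# Hard-core placement inside a horizontal band, vertically inset by `pad`
# so somata stay within the band.
place_in_band <- function(n, width, top, h, d_min, margin_x = 0, pad = 0,
                          max_attempts = 10000L) {
  if (n == 0L) return(list(x = numeric(0), y = numeric(0)))
  pad <- min(h / 2 * 0.9, pad)
  x <- numeric(n); y <- numeric(n); d2 <- d_min^2
  for (k in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      px <- margin_x + runif(1) * (width - 2 * margin_x)
      py <- top + pad + runif(1) * (h - 2 * pad)
      if (k == 1L || min((x[1:(k - 1)] - px)^2 + (y[1:(k - 1)] - py)^2) >= d2) {
        x[k] <- px; y[k] <- py; placed <- TRUE
        break
      }
    }
    if (!placed) abort(sprintf("could not place %d somata in the MP band", n))
  }
  list(x = x, y = y)
}

#' Muscle layer thickness from a cross-section
#'
#' Measures the vertical extent of the circular (`"cm"`) or longitudinal
#' (`"lm"`) muscle band along evenly spaced vertical transects of the smooth
#' muscle channel, and returns the mean thickness in micrometres. Two
#' transects per section mirrors measuring at two locations per cryosection.
#'
#' @param image An [image_stack()] from [render_cross_section()] or a
#'   matrix.
#' @param layer `"cm"` (upper band) or `"lm"` (lower band).
#' @param n_locations Number of transects (default 2).
#' @param channel Channel holding the muscle signal (default `"sma"`).
#' @param threshold Foreground cutoff on the 0-1 normalized channel.
#' @param pixel_size Required for plain matrices.
#' @return Mean thickness in micrometres, with per-transect values in the
#'   `"transects"` attribute.
#' @export
measure_muscle_thickness <- function(image, layer = c("cm", "lm"),
                                     n_locations = 2, channel = "sma",
                                     threshold = 0.5, pixel_size = NULL) {
  layer <- match.arg(layer)
  ps <- pixel_size %||% (if (inherits(image, "image_stack")) image$pixel_size else
    abort("`pixel_size` is required for a plain matrix"))
  img <- max_project(image, channel)
  rng <- range(img)
  if (diff(rng) <= 0) abort("muscle channel is empty")
  img <- (img - rng[1]) / diff(rng)
  nx <- ncol(img)
  cols <- round(seq_len(n_locations) / (n_locations + 1) * nx)
  th <- vapply(seq_along(cols), function(i) {
    prof <- img[, cols[i]] >= threshold
    runs <- rle(prof)
    on <- which(runs$values)
    if (length(on) < 2L)
      abort(sprintf("layer '%s' not resolvable on transect %d (found %d band(s))",
                    layer, i, length(on)))
    pick <- if (layer == "cm") on[1] else on[length(on)]
    runs$lengths[pick] * ps
  }, numeric(1))
  structure(mean(th), transects = th)
}

#' Nuclear count and density in a region of interest
#'
#' Blurs and thresholds a nuclear channel, counts connected components whose
#' centroids fall inside the region, and reports the areal density — the
#' automated equivalent of counting labelled nuclei over a region of about
#' 100,000 square micrometres.
#'
#' @param image An [image_stack()] or intensity matrix.
#' @param roi `c(x, y, width, height)` in micrometres (default: the whole
#'   image).
#' @param channel Channel holding the nuclear signal.
#' @param blur_sigma,threshold,min_size Segmentation parameters (micrometre
#'   units; `min_size` in square micrometres).
#' @param pixel_size Required for plain matrices.
#' @return One-row tibble: `count`, `roi_area` (square micrometres),
#'   `density` (per square micrometre).
#' @export
nuclear_density <- function(image, roi = NULL, channel = 1L, blur_sigma = 1,
                            threshold = "otsu", min_size = 4,
                            pixel_size = NULL) {
  ps <- pixel_size %||% (if (inherits(image, "image_stack")) image$pixel_size else
    abort("`pixel_size` is required for a plain matrix"))
  img <- max_project(image, channel)
  ext <- c(ncol(img), nrow(img)) * ps
  if (is.null(roi)) roi <- c(0, 0, ext[1], ext[2])
  if (roi[1] < 0 || roi[2] < 0 || roi[1] + roi[3] > ext[1] + 1e-9 ||
      roi[2] + roi[4] > ext[2] + 1e-9)
    abort("`roi` lies outside the image")
  fg <- foreground_mask(img, ps, blur_sigma = blur_sigma, threshold = threshold)
  if (!any(fg$mask))
    return(tibble(count = 0L, roi_area = roi[3] * roi[4], density = 0))
  labels <- filter_min_size(as.matrix(EBImage::bwlabel(fg$mask)), min_size / ps^2)
  k <- max(labels)
  if (k == 0L)
    return(tibble(count = 0L, roi_area = roi[3] * roi[4], density = 0))
  seg <- new_segmentation(labels, ps, list())
  cen <- seg$centroids
  inside <- cen$x >= roi[1] & cen$x < roi[1] + roi[3] &
    cen$y >= roi[2] & cen$y < roi[2] + roi[4]
  tibble(count = sum(inside), roi_area = roi[3] * roi[4],
         density = sum(inside) / (roi[3] * roi[4]))
}
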