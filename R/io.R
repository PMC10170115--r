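#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are rescaled to `[0, 1]` for storage; the scale factor,
#' pixel size, z-step and channel layout go to `<path>.json` so the stack
#' round-trips exactly up to the 32-bit float storage.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  pages <- list(); layout <- list()
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    layout[[ch]] <- dim(a)[3]
    for (k in seq_len(dim(a)[3])) pages[[length(pages) + 1L]] <- a[, , k]
  }
  scale <- max(1, vapply(pages, max, numeric(1)))
  pages <- lapply(pages, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size = stack$pixel_size, z_step = stack$z_step,
         scale = scale, channels = layout),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  chans <- list(); at <- 1L
  for (ch in names(meta$channels)) {
    nz <- meta$channels[[ch]]
    a <- array(0, c(dim(pages[[1]]), nz))
    for (k in seq_len(nz)) { a[, , k] <- pages[[at]] * meta$scale; at <- at + 1L }
    chans[[ch]] <- a
  }
  image_stack(chans, meta$pixel_size, meta$z_step)
}

#' Write / read a point pattern as CSV with a JSON sidecar
#'
#' @param pattern An `ens_pattern`.
#' @param path Output CSV path; the window and metadata go to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_point_pattern <- function(pattern, path) {
  utils::write.csv(as.data.frame(pattern), path, row.names = FALSE)
  jsonlite::write_json(
    list(window = pattern_window(pattern),
         d_min = attr(pattern, "d_min"),
         meta = attr(pattern, "meta")),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_point_pattern
#' @export
read_point_pattern <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  as_ens_pattern(df, window = meta$window,
                 d_min = meta$d_min %||% NA_real_,
                 meta = as.list(meta$meta))
}

#' Write an STM as TIFF plus JSON calibration
#'
#' @param stm An `ens_stm`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stm <- function(stm, path) {
  scale <- max(stm$diameter, na.rm = TRUE)
  m <- stm$diameter / scale
  m[is.na(m)] <- 0
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = scale, frame_rate = stm$frame_rate,
         bin_size = stm$bin_size, condition = stm$condition,
         valid = stm$valid),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stm
#' @export
read_stm <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * meta$scale
  structure(list(diameter = m,
                 times = (seq_len(nrow(m)) - 1) / meta$frame_rate,
                 x = (seq_len(ncol(m)) - 0.5) * meta$bin_size,
                 valid = meta$valid, frame_rate = meta$frame_rate,
                 bin_size = meta$bin_size, condition = meta$condition),
            class = "ens_stm")
}
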