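# Brute-force pairwise-offset histogram: the independent O(n^2) oracle for
# the raw CIF, written as an explicit double loop.
cif_oracle <- function(x, y, L, bin) {
  nb <- as.integer(round(2 * L / bin))
  out <- matrix(0L, nb, nb)
  n <- length(x)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx <= -L || dx >= L || dy <= -L || dy >= L) next
      ix <- floor((dx + L) / bin) + 1L
      iy <- floor((dy + L) / bin) + 1L
      out[ix, iy] <- out[ix, iy] + 1L
    }
  }
  out
}

# Brute-force minimum pairwise distance.
min_dist_oracle <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(Inf)
  best <- Inf
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      best <- min(best, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  best
}

# Match each truth point to the nearest measured centroid and return the
# distances (μm).
match_distances <- function(truth, measured) {
  vapply(seq_len(nrow(truth)), function(i)
    min(sqrt((measured$x - truth$x[i])^2 + (measured$y - truth$y[i])^2)),
    numeric(1))
}

# Single-channel stack with disks at given centres (μm), used where a
# hand-built image is clearer than the full renderer.
disk_stack <- function(centres, radius = 6.63, dim_um = c(200, 200),
                       pixel_size = 1, value = 1) {
  ny <- dim_um[2] / pixel_size
  nx <- dim_um[1] / pixel_size
  m <- matrix(0, ny, nx)
  for (i in seq_len(nrow(centres))) {
    for (r in 1:ny) for (c in 1:nx) {
      px <- (c - 0.5) * pixel_size
      py <- (r - 0.5) * pixel_size
      if ((px - centres$x[i])^2 + (py - centres$y[i])^2 <= radius^2)
        m[r, c] <- value
    }
  }
  image_stack(list(huc = m), pixel_size)
}
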