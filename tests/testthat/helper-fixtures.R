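# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# Cube in which every pixel carries the same spectrum.
uniform_cube <- function(spectrum, ny = 4, nx = 5,
                         axis = wavelength_axis(n_channels = length(spectrum))) {
  data <- array(rep(spectrum, each = ny * nx), c(1, ny, nx, length(spectrum)))
  spectral_image(data, axis)
}

# Phasor field with prescribed coordinates (one column of pixels).
fake_field <- function(g, s, intensity = rep(1, length(g)),
                       harmonic = 2L) {
  n <- length(g)
  structure(
    list(g = array(g, c(1, n, 1)), s = array(s, c(1, n, 1)),
         intensity_sum = array(intensity, c(1, n, 1)),
         null = array(intensity <= 0, c(1, n, 1)),
         harmonic = harmonic),
    class = "phasor_field"
  )
}

# Histogram object with prescribed counts (for gradient/apex tests).
fake_hist <- function(counts) {
  n <- nrow(counts)
  breaks <- seq(-1, 1, length.out = n + 1)
  structure(
    list(counts = counts, breaks = breaks,
         centers = (breaks[-1] + breaks[-(n + 1)]) / 2,
         bin_index = NULL, n_bins = n, total_count = sum(counts)),
    class = "phasor_histogram"
  )
}

# Logical mask erosion by `k` pixels (guards region statistics against
# median-filter cross-talk at region boundaries).
erode_mask <- function(m, k = 2) {
  for (rep in seq_len(k)) {
    p <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
    n <- nrow(m); q <- ncol(m)
    m <- m & p[1:n, 2:(q + 1)] & p[3:(n + 2), 2:(q + 1)] &
      p[2:(n + 1), 1:q] & p[2:(n + 1), 3:(q + 2)]
  }
  m
}

# Straight-from-formula phasor of a single spectrum (independent oracle).
phasor_oracle <- function(I, k, dl = 1) {
  N <- length(I)
  c_idx <- 0:(N - 1)
  tot <- sum(I * dl)
  c(sum(I * cos(2 * pi * k * c_idx / N) * dl) / tot,
    sum(I * sin(2 * pi * k * c_idx / N) * dl) / tot)
}

# Image with three horizontal bands of given colors; masks returned too.
banded_image <- function(colors, rows_per_band = 4, nx = 6) {
  ny <- rows_per_band * 3
  img <- array(0, c(ny, nx, 3))
  masks <- list()
  for (b in 1:3) {
    rows <- (b - 1) * rows_per_band + seq_len(rows_per_band)
    for (c in 1:3) img[rows, , c] <- colors[[b]][c]
    m <- matrix(FALSE, ny, nx)
    m[rows, ] <- TRUE
    masks[[b]] <- m
  }
  list(img = img, masks = masks)
}
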