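#' Spectral phasor transform
#'
#' Discrete Fourier transforms each pixel spectrum into normalized sine and
#' cosine coefficients at harmonic `k`:
#' \deqn{g = \frac{\sum_c I(\lambda_c)\cos(2\pi k c/N)\,\Delta\lambda}
#'                {\sum_c I(\lambda_c)\,\Delta\lambda}, \qquad
#'       s = \frac{\sum_c I(\lambda_c)\sin(2\pi k c/N)\,\Delta\lambda}
#'                {\sum_c I(\lambda_c)\,\Delta\lambda}}
#' with channel index `c = 0 .. N-1`. The transform is linear in the
#' spectrum, so mixtures of two spectra fall on the segment joining the pure
#' phasors, and every nonnegative spectrum maps inside the unit disc. A flat
#' spectrum maps exactly to the origin.
#'
#' Zero-intensity pixels have no defined phasor (the normalization is 0/0);
#' they carry the sentinel `(g, s) = (0, 0)` and are flagged `null`.
#'
#' @param cube a [spectral_image()].
#' @param harmonic Fourier harmonic `k`, one of 1, 2, 3. Default 2.
#' @return an object of class `phasor_field`: arrays `g`, `s`,
#'   `intensity_sum` (each `z, y, x`), logical array `null`, and `harmonic`.
#' @export
spectral_phasor <- function(cube, harmonic = 2L) {
  stopifnot(inherits(cube, "spectral_image"))
  harmonic <- as.integer(harmonic)
  if (!harmonic %in% 1:3)
    stop("`harmonic` must be 1, 2 or 3", call. = FALSE)
  d <- dim(cube$data)
  N <- d[4L]
  dl <- cube$axis$bandwidth
  cidx <- 0:(N - 1L)
  co <- cos(2 * pi * harmonic * cidx / N)
  si <- sin(2 * pi * harmonic * cidx / N)
  M <- matrix(cube$data, prod(d[1:3]), N)
  tot <- rowSums(M) * dl
  nullv <- tot <= 0
  if (all(nullv))
    warning("cube has zero total intensity everywhere; all phasors are null",
            call. = FALSE)
  g <- s <- numeric(length(tot))
  ok <- !nullv
  g[ok] <- (M[ok, , drop = FALSE] %*% co) * dl / tot[ok]
  s[ok] <- (M[ok, , drop = FALSE] %*% si) * dl / tot[ok]
  sp <- d[1:3]
  structure(
    list(
      g = array(g, sp), s = array(s, sp),
      intensity_sum = array(tot, sp),
      null = array(nullv, sp),
      harmonic = harmonic
    ),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  d <- dim(x$g)
  cat(sprintf("<phasor_field> z=%d y=%d x=%d, harmonic k=%d, %d null voxels\n",
              d[1], d[2], d[3], x$harmonic, sum(x$null)))
  invisible(x)
}

#' Median-filter denoising in phasor space
#'
#' Applies a 2D median filter independently to the `g` and `s` planes of
#' each z-slice, `cycles` times. Filtering in phasor space reduces the
#' scatter of the phasor cloud caused by photon noise while leaving the
#' intensity image untouched, so the operation is spatially lossless: no
#' pixel moves and `intensity_sum` is unchanged. Null pixels stay null with
#' the sentinel `(0, 0)`.
#'
#' @param field a `phasor_field`.
#' @param cycles number of filter passes, 0 to 5 (0 returns the field
#'   unchanged). Default 1.
#' @param kernel odd window size >= 3. Default 3.
#' @return the denoised `phasor_field`.
#' @export
phasor_denoise <- function(field, cycles = 1L, kernel = 3L) {
  stopifnot(inherits(field, "phasor_field"))
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 0L || cycles > 5L)
    stop("`cycles` must be between 0 and 5", call. = FALSE)
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L)
    stop("`kernel` must be an odd integer >= 3", call. = FALSE)
  if (cycles == 0L) return(field)
  nz <- dim(field$g)[1L]
  for (cyc in seq_len(cycles)) {
    for (z in seq_len(nz)) {
      field$g[z, , ] <- median_filter_2d(field$g[z, , ], kernel)
      field$s[z, , ] <- median_filter_2d(field$s[z, , ], kernel)
    }
  }
  field$g[field$null] <- 0
  field$s[field$null] <- 0
  field
}

#' 2D phasor histogram
#'
#' Bins the non-null phasors of a field on a regular `n_bins` x `n_bins`
#' grid covering the square `[-1, 1] x [-1, 1]`. Rows index `g`, columns
#' index `s`. The per-voxel bin assignment is retained so lookup-table
#' rendering can color each image pixel by its bin.
#'
#' @param field a `phasor_field`.
#' @param n_bins number of bins per axis, >= 2. Default 256.
#' @return an object of class `phasor_histogram`: `counts` (`n_bins` x
#'   `n_bins`), `breaks`, `centers` (bin-center coordinates), `bin_index`
#'   (linear bin id per voxel, `NA` for null voxels), `n_bins`,
#'   `total_count`.
#' @export
phasor_histogram <- function(field, n_bins = 256L) {
  stopifnot(inherits(field, "phasor_field"))
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("`n_bins` must be an integer >= 2", call. = FALSE)
  ig <- bin_of(field$g, n_bins)
  is <- bin_of(field$s, n_bins)
  lin <- (is - 1L) * n_bins + ig
  lin[field$null] <- NA_integer_
  counts <- matrix(tabulate(lin[!is.na(lin)], nbins = n_bins * n_bins),
                   n_bins, n_bins)
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  structure(
    list(
      counts = counts,
      breaks = breaks,
      centers = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
      bin_index = array(lin, dim(field$g)),
      n_bins = n_bins,
      total_count = sum(counts)
    ),
    class = "phasor_histogram"
  )
}

# Map coordinates in [-1, 1] to bin 1..n (values outside clipped to the
# boundary bins; the right edge closes the last bin).
bin_of <- function(x, n) {
  i <- floor((x + 1) / 2 * n) + 1L
  i[i < 1L] <- 1L
  i[i > n] <- n
  storage.mode(i) <- "integer"
  i
}

#' @export
print.phasor_histogram <- function(x, ...) {
  cat(sprintf("<phasor_histogram> %d x %d bins on [-1,1]^2, %d voxels\n",
              x$n_bins, x$n_bins, x$total_count))
  invisible(x)
}

#' Export a phasor histogram as a data frame
#'
#' One row per occupied bin, with bin-center coordinates and counts;
#' convenient for CSV export and plotting.
#'
#' @param x a `phasor_histogram`.
#' @param ... unused.
#' @export
as.data.frame.phasor_histogram <- function(x, ...) {
  occ <- which(x$counts > 0, arr.ind = TRUE)
  data.frame(
    g = x$centers[occ[, 1L]],
    s = x$centers[occ[, 2L]],
    count = x$counts[occ]
  )
}

#' Cartesian to polar phasor coordinates
#'
#' Quadrant-aware conversion: `r = sqrt(g^2 + s^2)` and `theta` the angle of
#' `(g, s)` mapped to `[0, 2*pi)`. The origin maps to `(r = 0, theta = 0)`
#' by convention.
#'
#' @param g,s numeric vectors or arrays of phasor coordinates.
#' @return a list with components `r` and `theta` of the same shape.
#' @export
to_polar <- function(g, s) {
  r <- sqrt(g^2 + s^2)
  theta <- atan2(s, g) %% (2 * pi)
  theta[r == 0] <- 0
  list(r = r, theta = theta)
}
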