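# Simulated Hyperspectral Test Chart (SHTC): the fixture generator that
# makes the whole pipeline testable without microscopy data.

#' Gaussian surrogate emission spectrum
#'
#' Parametric stand-in for a fluorophore emission spectrum: a Gaussian of
#' given peak wavelength, width (sigma) and amplitude. The defaults used by
#' the chart emulate CFP-, YFP- and RFP-like fluorophores (peaks 475, 527,
#' 580 nm, width 15 nm).
#'
#' @param peak peak wavelength (nm).
#' @param width Gaussian sigma (nm), > 0.
#' @param amplitude peak intensity (arbitrary photon units), >= 0.
#' @export
spectrum_model <- function(peak, width = 15, amplitude = 1) {
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  structure(list(peak = peak, width = width, amplitude = amplitude),
            class = "spectrum_model")
}

#' Sample a spectrum model on a wavelength axis
#'
#' @param model a [spectrum_model()].
#' @param axis a [wavelength_axis()].
#' @return numeric vector of length `axis$n_channels`.
#' @export
gaussian_spectrum <- function(model, axis = wavelength_axis()) {
  stopifnot(inherits(model, "spectrum_model"), inherits(axis, "wavelength_axis"))
  model$amplitude * exp(-(axis$centers - model$peak)^2 / (2 * model$width^2))
}

default_shift_grid <- function(bandwidth = 8.9) {
  # graded spectral overlap across the 3x3 cells: shifts are multiples of
  # the channel bandwidth, zero at the center cell (which carries the
  # unshifted base spectra); positive entries push S1 up and S3 down in
  # wavelength, increasing overlap with S2
  m <- matrix(c(-4, -3, -2, -1, 0, 1, 2, 3, 4), 3, 3, byrow = TRUE)
  m * bandwidth
}

#' Chart layout and spectra
#'
#' Specification of the simulated test chart: a `grid x grid` arrangement of
#' square cells, each holding three concentric square regions (outer ring
#' width 25 px, middle ring 15 px, center square 20 x 20 px for the default
#' 100 px cells) carrying three spectra. Per cell, the S1 and S3 peaks are
#' shifted by `d1` and `d2` nanometers relative to their base positions;
#' the center cell is unshifted.
#'
#' @param size chart side length in pixels (default 300).
#' @param grid cells per side (default 3).
#' @param base list of three [spectrum_model()]s (S1, S2, S3).
#' @param d1,d2 peak shifts (nm) for S1 (outer region) and S3 (center
#'   square): scalars or `grid x grid` matrices. Positive `d1` moves the S1
#'   peak up in wavelength, positive `d2` moves the S3 peak down, both
#'   toward S2. Defaults give a graded overlap across cells with the center
#'   cell unshifted.
#' @export
shtc_spec <- function(size = 300L, grid = 3L,
                      base = list(spectrum_model(475), spectrum_model(527),
                                  spectrum_model(580)),
                      d1 = default_shift_grid(), d2 = default_shift_grid()) {
  size <- as.integer(size); grid <- as.integer(grid)
  if (size %% grid != 0L) stop("`size` must be a multiple of `grid`", call. = FALSE)
  if (length(base) != 3L || !all(vapply(base, inherits, TRUE, "spectrum_model")))
    stop("`base` must be a list of three spectrum_model objects", call. = FALSE)
  expand <- function(d) {
    if (length(d) == 1L) d <- matrix(d, grid, grid)
    if (!all(dim(d) == c(grid, grid)))
      stop("shift grids must be scalar or grid x grid matrices", call. = FALSE)
    d
  }
  structure(list(size = size, grid = grid, base = base,
                 d1 = expand(d1), d2 = expand(d2)),
            class = "shtc_spec")
}

#' Uniform-overlap chart specification
#'
#' Convenience constructor for separation benchmarks: all cells identical,
#' with three equal-width spectra whose maxima sit at `peak - d1`, `peak`
#' and `peak + d2` nm. `d1 = 0, d2 = 8.9` gives the high-overlap regime
#' (maxima within one channel bandwidth); `d1 = 17.8, d2 = 35.6` the
#' moderate-overlap regime.
#'
#' @param d1,d2 peak offsets (nm) of S1 (below) and S3 (above) relative to
#'   the central spectrum.
#' @param peak central (S2) peak wavelength (nm).
#' @param width shared Gaussian sigma (nm).
#' @param size,grid chart geometry.
#' @export
shtc_overlap_chart <- function(d1, d2, peak = 527, width = 15,
                               size = 300L, grid = 3L) {
  shtc_spec(size = size, grid = grid,
            base = list(spectrum_model(peak - d1, width),
                        spectrum_model(peak, width),
                        spectrum_model(peak + d2, width)),
            d1 = 0, d2 = 0)
}

cell_region_masks <- function(cell) {
  # concentric squares: outer ring 1/4 of the cell side, middle ring 3/20,
  # center square 1/5 (25 / 15 / 20 px for a 100 px cell)
  o <- round(cell * 0.25); m <- round(cell * 0.15)
  inner1 <- (o + 1L):(cell - o)              # middle square extent
  inner2 <- (o + m + 1L):(cell - o - m)      # center square extent
  outer <- matrix(TRUE, cell, cell)
  outer[inner1, inner1] <- FALSE
  middle <- matrix(FALSE, cell, cell)
  middle[inner1, inner1] <- TRUE
  middle[inner2, inner2] <- FALSE
  center <- matrix(FALSE, cell, cell)
  center[inner2, inner2] <- TRUE
  list(outer = outer, middle = middle, center = center)
}

#' Build the Simulated Hyperspectral Test Chart
#'
#' Generates a noiseless `size x size x N` spectral cube laid out as a
#' `grid x grid` array of cells; each cell carries the (per-cell shifted)
#' S1 spectrum in its outer ring, S2 in the middle ring, and S3 in the
#' center square. The three region masks (chart-wide unions over cells) are
#' returned for use with [separation_accuracy()].
#'
#' @param spec an [shtc_spec()] (or [shtc_overlap_chart()]).
#' @param axis a [wavelength_axis()].
#' @return a [spectral_image()] with an extra field `regions`: list of
#'   logical `(size, size)` masks `Q1` (outer), `Q2` (middle), `Q3`
#'   (center).
#' @export
build_shtc <- function(spec = shtc_spec(), axis = wavelength_axis()) {
  stopifnot(inherits(spec, "shtc_spec"), inherits(axis, "wavelength_axis"))
  cell <- spec$size %/% spec$grid
  masks <- cell_region_masks(cell)
  N <- axis$n_channels
  lambda_min <- min(axis$centers); lambda_max <- max(axis$centers)
  cube <- array(0, c(1L, spec$size, spec$size, N))
  Q1 <- Q2 <- Q3 <- matrix(FALSE, spec$size, spec$size)
  for (i in seq_len(spec$grid)) {
    for (j in seq_len(spec$grid)) {
      peaks <- c(spec$base[[1L]]$peak + spec$d1[i, j],
                 spec$base[[2L]]$peak,
                 spec$base[[3L]]$peak - spec$d2[i, j])
      if (any(peaks < lambda_min | peaks > lambda_max))
        stop(sprintf("cell (%d,%d): shifted peak falls off the wavelength axis", i, j),
             call. = FALSE)
      sp <- lapply(1:3, function(q) {
        m <- spec$base[[q]]
        gaussian_spectrum(spectrum_model(peaks[q], m$width, m$amplitude), axis)
      })
      rows <- (i - 1L) * cell + seq_len(cell)
      cols <- (j - 1L) * cell + seq_len(cell)
      block <- array(0, c(cell, cell, N))
      for (q in 1:3) {
        mk <- masks[[q]]
        block <- block + outer(mk, sp[[q]])
      }
      cube[1L, rows, cols, ] <- block
      Q1[rows, cols] <- masks$outer
      Q2[rows, cols] <- masks$middle
      Q3[rows, cols] <- masks$center
    }
  }
  img <- spectral_image(cube, axis)
  img$regions <- list(Q1 = Q1, Q2 = Q2, Q3 = Q3)
  img
}

#' Add microscope-like noise to a spectral cube
#'
#' Emulates photon-counting statistics and detector read noise: intensities
#' are normalized to the cube maximum, each channel value is replaced by a
#' draw from `Poisson(photon_scale * I_norm)`, zero-mean Gaussian read
#' noise of standard deviation `read_sigma` is added, and the result is
#' clipped at zero. A seed is mandatory so every noisy cube is reproducible.
#'
#' @param cube a [spectral_image()].
#' @param photon_scale expected photon count at the cube's intensity
#'   maximum (> 0). Default 100.
#' @param read_sigma detector noise standard deviation in counts. Default 2.
#' @param seed integer RNG seed (required).
#' @return a [spectral_image()] in photon-count units (the `regions` field,
#'   if present, is carried over).
#' @export
add_noise <- function(cube, photon_scale = 100, read_sigma = 2, seed) {
  stopifnot(inherits(cube, "spectral_image"))
  if (photon_scale <= 0) stop("`photon_scale` must be > 0", call. = FALSE)
  if (read_sigma < 0) stop("`read_sigma` must be >= 0", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  mx <- max(cube$data)
  if (mx <= 0) stop("cube has zero intensity", call. = FALSE)
  lam <- as.vector(cube$data) / mx * photon_scale
  noisy <- stats::rpois(length(lam), lam)
  if (read_sigma > 0) noisy <- noisy + stats::rnorm(length(lam), 0, read_sigma)
  out <- cube
  out$data <- array(pmax(noisy, 0), dim(cube$data))
  out
}
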