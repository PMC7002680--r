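#' Wavelength axis of a hyperspectral detector
#'
#' Describes evenly spaced spectral channels. The default reproduces the
#' 32-channel lambda-mode detector configuration commonly used on spectral
#' confocal systems: 32 bins starting at 410.5 nm with 8.9 nm bandwidth,
#' spanning up to 694.9 nm.
#'
#' `centers` are `lambda0 + i * bandwidth` for `i = 0 .. n_channels - 1`
#' (410.5 ... 686.4 nm for the default axis); `wl_midpoints()` returns the
#' geometric bin midpoints (`lambda0 + bandwidth/2 + i * bandwidth`) for
#' users who prefer the bin-center convention.
#'
#' @param lambda0 wavelength of the first channel (nm).
#' @param bandwidth channel width (nm), > 0.
#' @param n_channels number of channels, >= 2.
#' @return an object of class `wavelength_axis` with fields `lambda0`,
#'   `bandwidth`, `n_channels` and `centers`.
#' @examples
#' ax <- wavelength_axis()
#' range(ax$centers)  # 410.5 686.4
#' @export
wavelength_axis <- function(lambda0 = 410.5, bandwidth = 8.9, n_channels = 32L) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 2L)
    stop("`n_channels` must be an integer >= 2", call. = FALSE)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("`bandwidth` must be > 0", call. = FALSE)
  structure(
    list(
      lambda0 = lambda0,
      bandwidth = bandwidth,
      n_channels = n_channels,
      centers = lambda0 + (seq_len(n_channels) - 1) * bandwidth
    ),
    class = "wavelength_axis"
  )
}

#' @rdname wavelength_axis
#' @param axis a `wavelength_axis`.
#' @export
wl_midpoints <- function(axis) axis$centers + axis$bandwidth / 2

#' @export
print.wavelength_axis <- function(x, ...) {
  cat(sprintf(
    "<wavelength_axis> %d channels, %.1f-%.1f nm, bandwidth %.2f nm\n",
    x$n_channels, x$lambda0, x$lambda0 + x$n_channels * x$bandwidth, x$bandwidth
  ))
  invisible(x)
}

#' Hyperspectral image cube
#'
#' Wraps a nonnegative intensity array `I(z, y, x, lambda)` together with its
#' wavelength axis. 2D and 3D arrays are promoted: `(y, x, lambda)` gets a
#' singleton z dimension.
#'
#' @param data numeric array, `(y, x, lambda)` or `(z, y, x, lambda)`, all
#'   values >= 0.
#' @param axis a [wavelength_axis()]; its channel count must match the last
#'   dimension of `data`.
#' @return an object of class `spectral_image` with fields `data`
#'   (`z, y, x, lambda`) and `axis`.
#' @export
spectral_image <- function(data, axis = wavelength_axis(n_channels = dim(data)[length(dim(data))])) {
  d <- dim(data)
  if (length(d) == 3L) {
    data <- array(data, c(1L, d))
    d <- dim(data)
  }
  if (length(d) != 4L)
    stop("`data` must be a (y, x, lambda) or (z, y, x, lambda) array", call. = FALSE)
  if (!inherits(axis, "wavelength_axis"))
    stop("`axis` must be a wavelength_axis", call. = FALSE)
  if (d[4L] != axis$n_channels)
    stop(sprintf("cube has %d spectral channels but axis declares %d",
                 d[4L], axis$n_channels), call. = FALSE)
  if (any(data < 0))
    stop("intensities must be nonnegative", call. = FALSE)
  structure(list(data = data, axis = axis), class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_image> z=%d y=%d x=%d lambda=%d\n", d[1], d[2], d[3], d[4]))
  print(x$axis)
  invisible(x)
}

#' Read a hyperspectral cube from a multichannel TIFF
#'
#' Reads an ImageJ-hyperstack style multichannel TIFF in which each plane is
#' one spectral channel. TIFF carries no wavelength metadata, so when `axis`
#' is not supplied the default 32-channel 410.5/8.9 nm axis convention is
#' attached (with the channel count taken from the file) and a warning is
#' emitted.
#'
#' @param path path to a multichannel TIFF file.
#' @param axis optional [wavelength_axis()]; must match the file's plane
#'   count.
#' @return a [spectral_image()].
#' @export
read_cube <- function(path, axis = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(planes)) planes <- list(planes)
  n <- length(planes)
  if (n < 2L)
    stop("cube must have at least 2 spectral channels (planes)", call. = FALSE)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse grayscale-as-RGB planes
    p
  })
  d <- dim(planes[[1L]])
  cube <- array(0, c(1L, d[1L], d[2L], n))
  for (i in seq_len(n)) cube[1L, , , i] <- planes[[i]]
  if (is.null(axis)) {
    warning(sprintf(
      "no wavelength metadata in '%s'; attaching default axis (410.5 nm start, 8.9 nm bandwidth, %d channels)",
      basename(path), n), call. = FALSE)
    axis <- wavelength_axis(410.5, 8.9, n)
  } else if (axis$n_channels != n) {
    stop(sprintf("file has %d planes but axis declares %d channels",
                 n, axis$n_channels), call. = FALSE)
  }
  spectral_image(cube, axis)
}

#' Write an RGB rendering to disk
#'
#' Writes an 8-bit PNG or TIFF. Values are quantized with round-half-up to
#' 255 levels, so a round-trip read agrees with the input to within 1/255.
#'
#' @param image numeric array `(y, x, 3)` (or `(1, y, x, 3)`) with values in
#'   `[0, 1]`.
#' @param path output file path.
#' @param format `"png"` or `"tiff"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(image, path, format = c("png", "tiff")) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff" else "png"
  }
  format <- match.arg(format)
  d <- dim(image)
  if (length(d) == 4L && d[1L] == 1L) {
    image <- array(image[1L, , , ], d[-1L])
    d <- dim(image)
  }
  if (length(d) != 3L || d[3L] != 3L)
    stop("`image` must be a (y, x, 3) RGB array", call. = FALSE)
  if (any(!is.finite(image)) || any(image < 0) || any(image > 1))
    stop("RGB values must lie in [0, 1]", call. = FALSE)
  image <- round(image * 255) / 255
  if (format == "png") png::writePNG(image, path) else tiff::writeTIFF(image, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit RGB image written by [write_rgb()]
#'
#' @param path file path (PNG or TIFF).
#' @return numeric array `(y, x, 3)` in `[0, 1]`.
#' @export
read_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}
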