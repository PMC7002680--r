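#' Render a phasor field through a color lookup table
#'
#' Assigns every image pixel the LUT color of its phasor bin. With
#' `intensity_mode = "scaled"` the color is modulated by the pixel's
#' normalized integrated intensity (compromising brightness for structure);
#' `"flat"` returns the pure RGB mask, identical up to a per-pixel scalar
#' factor. Null pixels are black in both modes.
#'
#' @param field a `phasor_field`.
#' @param lut a [build_lut()] result.
#' @param intensity_mode `"scaled"` (default) or `"flat"`.
#' @return RGB array `(z, y, x, 3)` in `[0, 1]`.
#' @export
apply_lut <- function(field, lut, intensity_mode = c("scaled", "flat")) {
  stopifnot(inherits(field, "phasor_field"), inherits(lut, "color_lut"))
  intensity_mode <- match.arg(intensity_mode)
  n <- lut$n_bins
  lin <- (bin_of(as.vector(field$s), n) - 1L) * n + bin_of(as.vector(field$g), n)
  lin[as.vector(field$null)] <- NA_integer_
  lutm <- matrix(lut$rgb, n * n, 3L)
  rgbv <- matrix(0, length(lin), 3L)
  ok <- !is.na(lin)
  rgbv[ok, ] <- lutm[lin[ok], ]
  if (intensity_mode == "scaled") {
    w <- as.vector(field$intensity_sum)
    mx <- max(w)
    if (mx > 0) rgbv <- rgbv * (w / mx)
  }
  array(rgbv, c(dim(field$g), 3L))
}

#' Gaussian-kernel R/G/B centers
#'
#' Parameters of the TrueColor baseline: the center wavelength of each
#' R/G/B similarity kernel and the shared deviation `sigma`. Defaults are
#' 650/510/470 nm, `sigma = 50` nm.
#'
#' @param red,green,blue kernel center wavelengths (nm).
#' @param sigma kernel standard deviation (nm), > 0.
#' @export
kernel_centers <- function(red = 650, green = 510, blue = 470, sigma = 50) {
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  structure(list(red = red, green = green, blue = blue, sigma = sigma),
            class = "kernel_centers")
}

#' TrueColor rendering via Gaussian radial-basis kernels
#'
#' Baseline RGB compression of the spectral cube: each output channel
#' weights the spectrum by a Gaussian similarity kernel
#' `K_i = exp(-(x_i - x')^2 / (2 sigma^2))` centered at that channel's
#' wavelength `x'`, normalized to unit sum over spectral channels, and the
#' channel value is the kernel-weighted sum of the pixel's intensities.
#' The result is normalized by the global maximum, so it is linear in the
#' input spectrum up to that final scaling.
#'
#' @param cube a [spectral_image()].
#' @param centers a [kernel_centers()].
#' @return RGB array `(z, y, x, 3)` in `[0, 1]`.
#' @export
truecolor_gaussian <- function(cube, centers = kernel_centers()) {
  stopifnot(inherits(cube, "spectral_image"), inherits(centers, "kernel_centers"))
  wl <- cube$axis$centers
  K <- sapply(c(centers$red, centers$green, centers$blue), function(x0) {
    k <- exp(-(wl - x0)^2 / (2 * centers$sigma^2))
    k / sum(k)
  })
  d <- dim(cube$data)
  M <- matrix(cube$data, prod(d[1:3]), d[4L])
  out <- M %*% K
  mx <- max(out)
  if (mx > 0) out <- out / mx
  array(clamp(out), c(d[1:3], 3L))
}

#' Adaptive Gaussian-kernel centers from the dataset spectrum
#'
#' Computes the dataset-average spectrum, normalizes it to a maximum of 1,
#' and finds the left and right wavelengths where it crosses `fraction`
#' (linear interpolation between channel centers). The blue kernel is
#' centered at the left crossing, the red kernel at the right crossing, and
#' the green kernel halfway between them. If the spectrum never crosses
#' `fraction`, the axis endpoints are used with a warning.
#'
#' @param cube a [spectral_image()].
#' @param fraction crossing level in `(0, 1)`; 0.10, 0.20 and 0.30 are the
#'   typical choices.
#' @param sigma kernel deviation passed through to [kernel_centers()].
#' @return a [kernel_centers()].
#' @export
adaptive_centers <- function(cube, fraction = 0.10, sigma = 50) {
  stopifnot(inherits(cube, "spectral_image"))
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  d <- dim(cube$data)
  avg <- colMeans(matrix(cube$data, prod(d[1:3]), d[4L]))
  if (max(avg) <= 0) stop("cube has zero total intensity", call. = FALSE)
  avg <- avg / max(avg)
  wl <- cube$axis$centers
  cross_up <- function(i) {  # interpolate between channels i and i+1
    wl[i] + (fraction - avg[i]) / (avg[i + 1L] - avg[i]) * (wl[i + 1L] - wl[i])
  }
  above <- avg >= fraction
  if (!any(above)) {
    warning("average spectrum never reaches `fraction`; using axis endpoints",
            call. = FALSE)
    left <- wl[1L]; right <- wl[length(wl)]
  } else {
    iL <- which(above)[1L]
    left <- if (iL == 1L) wl[1L] else cross_up(iL - 1L)
    iR <- max(which(above))  # last channel at/above fraction
    right <- if (iR == length(wl)) wl[length(wl)] else
      wl[iR] + (avg[iR] - fraction) / (avg[iR] - avg[iR + 1L]) * (wl[iR + 1L] - wl[iR])
  }
  kernel_centers(red = right, green = (left + right) / 2, blue = left, sigma = sigma)
}

#' Visible-spectrum wavelength to RGB
#'
#' Classical piecewise-linear conversion of a wavelength to its perceived
#' RGB color (Bruton's mapping): violet 380-440, blue-cyan 440-490,
#' cyan-green 490-510, green-yellow 510-580, yellow-red 580-645, red
#' 645-780 nm, with linear intensity falloff below 420 nm and above 700 nm.
#' Wavelengths outside 380-780 nm return black.
#'
#' @param lambda wavelengths in nm (vector).
#' @return numeric matrix `(n, 3)` of RGB values in `[0, 1]`.
#' @export
wavelength_to_rgb <- function(lambda) {
  n <- length(lambda)
  r <- g <- b <- numeric(n)
  seg <- function(lo, hi) lambda >= lo & lambda < hi
  i <- seg(380, 440); r[i] <- -(lambda[i] - 440) / 60; b[i] <- 1
  i <- seg(440, 490); g[i] <- (lambda[i] - 440) / 50; b[i] <- 1
  i <- seg(490, 510); g[i] <- 1; b[i] <- -(lambda[i] - 510) / 20
  i <- seg(510, 580); r[i] <- (lambda[i] - 510) / 70; g[i] <- 1
  i <- seg(580, 645); r[i] <- 1; g[i] <- -(lambda[i] - 645) / 65
  i <- lambda >= 645 & lambda <= 780; r[i] <- 1
  fade <- rep(1, n)
  i <- seg(380, 420); fade[i] <- 0.3 + 0.7 * (lambda[i] - 380) / 40
  i <- lambda > 700 & lambda <= 780; fade[i] <- 0.3 + 0.7 * (780 - lambda[i]) / 80
  out <- lambda < 380 | lambda > 780
  fade[out] <- 0
  cbind(r = r * fade, g = g * fade, b = b * fade)
}

#' Peak-wavelength rendering
#'
#' Baseline that colors each pixel by the visible-spectrum color of the
#' channel at which its maximum intensity occurs (ties broken toward the
#' lowest wavelength). Invariant to per-pixel intensity scaling; pixels with
#' no signal are black.
#'
#' @param cube a [spectral_image()].
#' @return RGB array `(z, y, x, 3)` in `[0, 1]`.
#' @export
peak_wavelength_rgb <- function(cube) {
  stopifnot(inherits(cube, "spectral_image"))
  d <- dim(cube$data)
  M <- matrix(cube$data, prod(d[1:3]), d[4L])
  idx <- max.col(M, ties.method = "first")
  rgbv <- wavelength_to_rgb(cube$axis$centers[idx])
  rgbv[rowSums(M) <= 0, ] <- 0
  array(rgbv, c(d[1:3], 3L))
}

#' Maximum intensity projection of an RGB stack
#'
#' Projects a `(z, y, x, 3)` RGB stack to a single plane by keeping, per
#' pixel, the RGB triple of the z-plane with maximal luminance
#' (`0.299 R + 0.587 G + 0.114 B`), so projected pixels keep physically
#' co-located colors.
#'
#' @param stack RGB array `(z, y, x, 3)`.
#' @return RGB array `(y, x, 3)`.
#' @export
mip <- function(stack) {
  d <- dim(stack)
  if (length(d) == 3L) return(stack)
  if (length(d) != 4L || d[4L] != 3L)
    stop("`stack` must be a (z, y, x, 3) RGB array", call. = FALSE)
  if (d[1L] == 1L) return(array(stack[1L, , , ], d[-1L]))
  lum <- 0.299 * stack[, , , 1L] + 0.587 * stack[, , , 2L] + 0.114 * stack[, , , 3L]
  lum <- matrix(lum, d[1L], d[2L] * d[3L])
  zbest <- max.col(t(lum), ties.method = "first")
  npix <- d[2L] * d[3L]
  sm <- matrix(stack, d[1L], npix * 3L)
  pick <- sm[cbind(rep(zbest, 3L), seq_len(npix * 3L))]
  array(pick, c(d[2L], d[3L], 3L))
}
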