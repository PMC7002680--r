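SEER_MAPS <- c("gradient_descent", "gradient_ascent", "radial", "angular")

#' Jet colormap lookup
#'
#' Piecewise-linear jet ramp with fixed anchors
#' `0 -> (0,0,0.5)`, `0.125 -> (0,0,1)`, `0.375 -> (0,1,1)`,
#' `0.625 -> (1,1,0)`, `0.875 -> (1,0,0)`, `1 -> (0.5,0,0)`, so results do
#' not depend on any plotting library's palette implementation.
#'
#' @param v numeric vector of levels in `[0, 1]`; values outside are clamped
#'   (with a warning).
#' @return numeric matrix `(length(v), 3)` of RGB values in `[0, 1]`.
#' @export
jet_lookup <- function(v) {
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    warning("jet_lookup: values outside [0, 1] clamped", call. = FALSE)
    v <- clamp(v)
  }
  anchors <- c(0, 0.125, 0.375, 0.625, 0.875, 1)
  ra <- c(0, 0, 0, 1, 1, 0.5)
  ga <- c(0, 0, 1, 1, 0, 0)
  ba <- c(0.5, 1, 1, 0, 0, 0)
  cbind(
    r = stats::approx(anchors, ra, xout = v)$y,
    g = stats::approx(anchors, ga, xout = v)$y,
    b = stats::approx(anchors, ba, xout = v)$y
  )
}

#' Color of a phasor coordinate under a standard reference map
#'
#' Assigns a color to polar phasor coordinates following the four standard
#' reference maps. Hue tracks the phase angle (`hue = theta / 2pi`) for the
#' angular and both gradient maps; the radial map is a jet ramp in `r`:
#'
#' * `gradient_descent`: HSV `(theta/2pi, 1, 1 - 0.85 r)` -- bright at the
#'   center, enhancing subtle wavelength differences.
#' * `gradient_ascent`: HSV `(theta/2pi, 1, r)` -- dark at the center,
#'   enhancing differences at high intensity.
#' * `radial`: `jet_lookup(r)`, sensitive to intensity/magnitude only.
#' * `angular`: HSV `(theta/2pi, 1, 1)`, sensitive to phase only.
#'
#' Any coordinate outside the `r = 1` unit-circle boundary is set to black.
#'
#' @param r,theta polar phasor coordinates (see [to_polar()]); vectors.
#' @param map_name one of `"gradient_descent"`, `"gradient_ascent"`,
#'   `"radial"`, `"angular"`.
#' @return numeric matrix `(n, 3)` of RGB values in `[0, 1]`.
#' @export
standard_map_color <- function(r, theta, map_name = SEER_MAPS) {
  map_name <- match.arg(map_name)
  hue <- theta / (2 * pi)
  rc <- clamp(r)  # color rule evaluated on the disc; r > 1 blacked below
  rgb <- switch(map_name,
    gradient_descent = hsv_to_rgb(hue, 1, 1 - 0.85 * rc),
    gradient_ascent  = hsv_to_rgb(hue, 1, rc),
    angular          = hsv_to_rgb(hue, 1, rep(1, length(hue))),
    radial           = jet_lookup(rc)
  )
  out <- r > 1 + 1e-12
  if (any(out)) rgb[out, ] <- 0
  rgb
}

#' Gradient of phasor-histogram counts
#'
#' Computes the two-dimensional derivative of the histogram counts
#' `F(g, s)` with second-order accurate central differences at unit bin
#' spacing (one-sided differences at the grid boundary, where the central
#' stencil is undefined), then the gradient magnitude
#' `D = sqrt((dF/dg)^2 + (dF/ds)^2)`, normalized so `max(D) = 1`.
#'
#' @param hist a [phasor_histogram()].
#' @return an object of class `gradient_field`: `d` (normalized magnitude),
#'   `dFdg`, `dFds` (raw differences), `n_bins`.
#' @export
tensor_gradient <- function(hist) {
  stopifnot(inherits(hist, "phasor_histogram"))
  FF <- hist$counts
  n <- hist$n_bins
  dFdg <- matrix(0, n, n)  # along rows (g)
  dFds <- matrix(0, n, n)  # along columns (s)
  dFdg[2:(n - 1), ] <- (FF[3:n, ] - FF[1:(n - 2), ]) / 2
  dFdg[1, ] <- FF[2, ] - FF[1, ]
  dFdg[n, ] <- FF[n, ] - FF[n - 1, ]
  dFds[, 2:(n - 1)] <- (FF[, 3:n] - FF[, 1:(n - 2)]) / 2
  dFds[, 1] <- FF[, 2] - FF[, 1]
  dFds[, n] <- FF[, n] - FF[, n - 1]
  d <- sqrt(dFdg^2 + dFds^2)
  mx <- max(d)
  if (mx > 0) d <- d / mx else warning("all-zero histogram gradient", call. = FALSE)
  structure(list(d = d, dFdg = dFdg, dFds = dFds, n_bins = n),
            class = "gradient_field")
}

#' Tensor map rendering
#'
#' Recolors each image pixel by the normalized gradient magnitude of the
#' phasor histogram at the pixel's phasor bin, through the jet colormap.
#' Bins with equal gradient magnitude share one color, so the rendering acts
#' as a spectral edge detector: rare spectra sitting at the fringe of a
#' phasor cluster light up differently from the dense cluster core. Null
#' pixels are black.
#'
#' @param field a `phasor_field`.
#' @param hist the [phasor_histogram()] built from `field`.
#' @param grad optionally a precomputed [tensor_gradient()] of `hist`.
#' @return RGB array `(z, y, x, 3)` in `[0, 1]`.
#' @export
tensor_map_render <- function(field, hist, grad = tensor_gradient(hist)) {
  stopifnot(inherits(field, "phasor_field"), inherits(grad, "gradient_field"))
  if (grad$n_bins != hist$n_bins)
    stop("gradient field and histogram have different bin geometry", call. = FALSE)
  lin <- as.vector(hist$bin_index)
  rgbv <- matrix(0, length(lin), 3L)
  ok <- !is.na(lin)
  rgbv[ok, ] <- jet_lookup(grad$d[lin[ok]])
  dims <- dim(field$g)
  array(rgbv, c(dims, 3L))
}

#' Reference-map legend image
#'
#' Renders the color wheel of a lookup table (or of a bare standard map) on
#' an `n x n` grid over `[-1, 1]^2`, as shown in figure insets: the color
#' every phasor coordinate would receive, black outside the unit circle.
#'
#' @param lut a [build_lut()] result, or a map name for the standard wheel.
#' @param n grid resolution when `lut` is a map name.
#' @return RGB array `(n, n, 3)`; rows index `g`, columns `s`.
#' @export
lut_legend <- function(lut, n = 256L) {
  if (is.character(lut)) lut <- build_lut(lut, mode = "standard", n_bins = n)
  lut$rgb
}
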