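SEER_MODES <- c("standard", "scale", "morph_max", "morph_mass")

#' Bounding box of the occupied phasor bins
#'
#' Determines the axis-aligned box (width `omega`, height `h`) enclosing all
#' occupied (count > 0) histogram bins, the semi-axes `a = omega/2`,
#' `b = h/2` of the largest inscribed ellipse, and the box center. An
#' optional symmetric quantile trim guards against single stray bins.
#'
#' @param hist a [phasor_histogram()].
#' @param trim fraction in `[0, 0.5)` trimmed from each tail of the occupied
#'   bin coordinates (default 0: exact min/max).
#' @return an object of class `phasor_bbox` with fields `gmin`, `gmax`,
#'   `smin`, `smax`, `width`, `height`, `a`, `b`, `center`.
#' @export
phasor_bbox <- function(hist, trim = 0) {
  stopifnot(inherits(hist, "phasor_histogram"))
  if (trim < 0 || trim >= 0.5) stop("`trim` must be in [0, 0.5)", call. = FALSE)
  occ <- which(hist$counts > 0, arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("histogram is empty", call. = FALSE)
  gs <- hist$centers[occ[, 1L]]
  ss <- hist$centers[occ[, 2L]]
  if (trim > 0) {
    qg <- stats::quantile(gs, c(trim, 1 - trim), names = FALSE)
    qs <- stats::quantile(ss, c(trim, 1 - trim), names = FALSE)
  } else {
    qg <- range(gs); qs <- range(ss)
  }
  # pad by half a bin so single-bin clusters keep a nondegenerate box
  hb <- (hist$breaks[2L] - hist$breaks[1L]) / 2
  box <- list(gmin = qg[1L] - hb, gmax = qg[2L] + hb,
              smin = qs[1L] - hb, smax = qs[2L] + hb)
  box$width <- box$gmax - box$gmin
  box$height <- box$smax - box$smin
  box$a <- box$width / 2
  box$b <- box$height / 2
  box$center <- c(g = (box$gmin + box$gmax) / 2, s = (box$smin + box$smax) / 2)
  structure(box, class = "phasor_bbox")
}

#' Dataset box whose inscribed ellipse wraps all phasor points
#'
#' The box used by scale mode when derived automatically from the data:
#' starting from [phasor_bbox()], both semi-axes are dilated by the smallest
#' common factor that brings every occupied histogram bin inside the
#' inscribed ellipse, so the warped reference map wraps around the phasor
#' cloud and no data point falls outside the `r = 1` boundary (clusters at
#' the box corners would otherwise be clipped by the ellipse).
#'
#' @inheritParams phasor_bbox
#' @return a [phasor_bbox()] object (center unchanged, axes inflated).
#' @export
enclosing_bbox <- function(hist, trim = 0) {
  box <- phasor_bbox(hist, trim = trim)
  occ <- which(hist$counts > 0, arr.ind = TRUE)
  qg <- (hist$centers[occ[, 1L]] - box$center[["g"]]) / box$a
  qs <- (hist$centers[occ[, 2L]] - box$center[["s"]]) / box$b
  f <- max(sqrt(qg^2 + qs^2), 1)
  make_bbox(box$center[["g"]] - f * box$a, box$center[["g"]] + f * box$a,
            box$center[["s"]] - f * box$b, box$center[["s"]] + f * box$b)
}

#' Manually specified bounding box
#'
#' Builds the `phasor_bbox` used by scale mode from explicit limits, e.g. to
#' hold the color scaling constant across samples.
#'
#' @param gmin,gmax,smin,smax box limits in phasor coordinates.
#' @export
make_bbox <- function(gmin, gmax, smin, smax) {
  if (!(gmax > gmin && smax > smin))
    stop("degenerate bounding box", call. = FALSE)
  structure(
    list(gmin = gmin, gmax = gmax, smin = smin, smax = smax,
         width = gmax - gmin, height = smax - smin,
         a = (gmax - gmin) / 2, b = (smax - smin) / 2,
         center = c(g = (gmin + gmax) / 2, s = (smin + smax) / 2)),
    class = "phasor_bbox"
  )
}

#' Apex of the morph-mode shifted cone
#'
#' Computes the new map center used by morph mode: either the bin-center of
#' the highest-count histogram bin (`max`, ties broken toward the lowest bin
#' index) or the count-weighted centroid of the phasor coordinates (`mass`).
#'
#' @param hist a [phasor_histogram()].
#' @param method `"max"` or `"mass"`.
#' @return an object of class `apex_point` with fields `g` and `s`
#'   (`g^2 + s^2 < 1`).
#' @export
compute_apex <- function(hist, method = c("max", "mass")) {
  stopifnot(inherits(hist, "phasor_histogram"))
  method <- match.arg(method)
  if (hist$total_count == 0L) stop("histogram is empty", call. = FALSE)
  if (method == "max") {
    ij <- which(hist$counts == max(hist$counts), arr.ind = TRUE)[1L, ]
    gA <- hist$centers[ij[1L]]
    sA <- hist$centers[ij[2L]]
  } else {
    w <- hist$counts / hist$total_count
    gA <- sum(rowSums(w) * hist$centers)
    sA <- sum(colSums(w) * hist$centers)
  }
  if (gA^2 + sA^2 >= 1)
    stop("apex lies outside the unit disc", call. = FALSE)
  structure(list(g = gA, s = sA), class = "apex_point")
}

#' Scale-mode coordinate transform
#'
#' Warps the reference map so that its unit circle becomes the largest
#' ellipse inscribed in the data's bounding box: a point `p` is recentred at
#' the box center and its radius rescaled by the local ellipse radius, so
#' points on the ellipse boundary map exactly to `r = 1` (the map edge) and
#' the box-center maps to the map origin. With the box equal to the full
#' `[-1, 1]^2` square the transform is the identity.
#'
#' @param g,s phasor coordinates (vectors).
#' @param box a [phasor_bbox()] or [make_bbox()].
#' @return list with transformed coordinates `g`, `s` (and `r`, `theta`).
#' @export
scale_transform <- function(g, s, box) {
  stopifnot(inherits(box, "phasor_bbox"))
  if (box$a <= 0 || box$b <= 0) stop("degenerate bounding box", call. = FALSE)
  qg <- g - box$center[["g"]]
  qs <- s - box$center[["s"]]
  r_o <- sqrt((qg / box$a)^2 + (qs / box$b)^2)
  theta <- atan2(qs, qg) %% (2 * pi)
  theta[r_o == 0] <- 0
  list(g = r_o * cos(theta), s = r_o * sin(theta), r = r_o, theta = theta)
}

#' Morph-mode coordinate transform
#'
#' Shifted-cone warp: the reference map is viewed as a right cone over the
#' unit disc whose apex projects onto the origin; morph mode moves the apex
#' to `A = (g_A, s_A)`, producing an oblique cone whose horizontal sections
#' project to circles of radius `1 - alpha` centered at `alpha * A`. For an
#' input point `p` the section parameter `alpha` solves
#' \deqn{(g - \alpha g_A)^2 + (s - \alpha s_A)^2 = (1 - \alpha)^2}
#' (quadratic in `alpha`; the root in `[0, 1)` is taken, the smaller when
#' both qualify) and the morphed coordinate is `p - alpha * A`. Points on
#' the unit circle have `alpha = 0` and are fixed; the apex itself maps to
#' the map origin; apex `(0, 0)` gives the identity. Points outside the
#' unit disc are passed through unchanged (they render black).
#'
#' @param g,s phasor coordinates (vectors).
#' @param apex an [compute_apex()] result or list with fields `g`, `s`
#'   (`g^2 + s^2 < 1`).
#' @return list with transformed `g`, `s` (and `r`, `theta`, `alpha`).
#' @export
morph_transform <- function(g, s, apex) {
  gA <- apex$g; sA <- apex$s
  if (gA^2 + sA^2 >= 1) stop("|apex| must be < 1", call. = FALSE)
  n <- length(g)
  alpha <- numeric(n)
  if (gA != 0 || sA != 0) {
    a <- gA^2 + sA^2 - 1                 # < 0
    b <- 2 * (1 - g * gA - s * sA)
    cc <- g^2 + s^2 - 1
    inside <- cc <= 0
    disc <- pmax(b^2 - 4 * a * cc, 0)
    sq <- sqrt(disc)
    r1 <- (-b + sq) / (2 * a)
    r2 <- (-b - sq) / (2 * a)
    lo <- pmin(r1, r2); hi <- pmax(r1, r2)
    tol <- 1e-12
    pick <- ifelse(lo >= -tol & lo < 1, pmax(lo, 0),
                   ifelse(hi >= -tol & hi < 1, pmax(hi, 0), 0))
    alpha[inside] <- pick[inside]
    at_apex <- inside & (g - gA)^2 + (s - sA)^2 < 1e-24
    alpha[at_apex] <- NA  # resolved below: apex maps to the origin
  }
  g_o <- g - alpha * gA
  s_o <- s - alpha * sA
  g_o[is.na(alpha)] <- 0
  s_o[is.na(alpha)] <- 0
  pol <- to_polar(g_o, s_o)
  list(g = g_o, s = s_o, r = pol$r, theta = pol$theta, alpha = alpha)
}

#' Bake a reference map and contrast mode into a color lookup table
#'
#' For every bin center of the phasor-histogram grid, applies the mode's
#' coordinate transform (`standard`: none; `scale`: [scale_transform()] with
#' the data's bounding box; `morph_max`/`morph_mass`: [morph_transform()]
#' with the corresponding apex) and then the reference-map color rule.
#' Coordinates landing outside the unit circle are black. The standard-mode
#' LUT depends only on `map_name` and `n_bins`, so it is identical across
#' datasets; the adaptive modes require a histogram (or explicit `box` /
#' `apex` parameters, e.g. to fix the scaling across samples).
#'
#' @param map_name one of `"gradient_descent"`, `"gradient_ascent"`,
#'   `"radial"`, `"angular"`.
#' @param mode one of `"standard"`, `"scale"`, `"morph_max"`, `"morph_mass"`.
#' @param hist a [phasor_histogram()]; required for the adaptive modes
#'   unless `box`/`apex` is supplied.
#' @param box optional [phasor_bbox()] override for scale mode.
#' @param apex optional apex override for the morph modes.
#' @param n_bins LUT grid size; taken from `hist` when given.
#' @param trim quantile trim passed to [phasor_bbox()].
#' @return an object of class `color_lut`: `rgb` (`n_bins, n_bins, 3`),
#'   `map_name`, `mode`, `n_bins`, and the mode parameters used.
#' @export
build_lut <- function(map_name = SEER_MAPS, mode = SEER_MODES, hist = NULL,
                      box = NULL, apex = NULL, n_bins = NULL, trim = 0) {
  map_name <- match.arg(map_name)
  mode <- match.arg(mode)
  if (is.null(n_bins)) n_bins <- if (!is.null(hist)) hist$n_bins else 256L
  if (!is.null(hist) && hist$n_bins != n_bins)
    stop("`n_bins` disagrees with the histogram geometry", call. = FALSE)
  centers <- if (!is.null(hist)) hist$centers else {
    br <- seq(-1, 1, length.out = n_bins + 1L)
    (br[-1L] + br[-(n_bins + 1L)]) / 2
  }
  gg <- rep(centers, times = n_bins)        # row index varies fastest: g
  ss <- rep(centers, each = n_bins)
  params <- list()
  if (mode == "scale") {
    if (is.null(box)) {
      if (is.null(hist)) stop("scale mode needs a histogram or a box", call. = FALSE)
      box <- enclosing_bbox(hist, trim = trim)
    }
    tr <- scale_transform(gg, ss, box)
    params$box <- box
  } else if (mode %in% c("morph_max", "morph_mass")) {
    if (is.null(apex)) {
      if (is.null(hist)) stop("morph modes need a histogram or an apex", call. = FALSE)
      apex <- compute_apex(hist, if (mode == "morph_max") "max" else "mass")
    }
    tr <- morph_transform(gg, ss, apex)
    params$apex <- apex
  } else {
    tr <- to_polar(gg, ss)
  }
  rgb <- standard_map_color(tr$r, tr$theta, map_name)
  structure(
    list(rgb = array(rgb, c(n_bins, n_bins, 3L)),
         map_name = map_name, mode = mode, n_bins = n_bins, params = params),
    class = "color_lut"
  )
}

#' @export
print.color_lut <- function(x, ...) {
  cat(sprintf("<color_lut> map=%s mode=%s, %d x %d bins\n",
              x$map_name, x$mode, x$n_bins, x$n_bins))
  invisible(x)
}
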