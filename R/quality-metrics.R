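# No-reference color image quality metrics and the spectral-separation
# statistic used to compare renderings. Moment/extremum metrics operate on
# the 0-255 scale with natural logarithms; eps guards every log/division
# (1e-4 on the [0,1] scale, i.e. 0.0255 in 0-255 units).

METRIC_EPS <- 1e-4 * 255
NTSC_WEIGHTS <- c(r = 0.299, g = 0.587, b = 0.114)
CQE_COEF <- c(colorfulness = 0.4358, sharpness = 0.1722, contrast = 0.3920)

as_rgb_plane <- function(img) {
  d <- dim(img)
  if (length(d) == 4L) {
    if (d[1L] != 1L)
      stop("metrics expect a single-plane RGB image; project z-stacks first (see mip())",
           call. = FALSE)
    img <- array(img[1L, , , ], d[-1L])
  }
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("expected a (y, x, 3) RGB array", call. = FALSE)
  img
}

#' Block tiling of an image
#'
#' Blocks used by the extremum-based metrics: `k1` blocks along rows and
#' `k2` along columns; remainder pixels are merged into the last block.
#'
#' @param k1,k2 block counts (>= 1). Default 8 x 8.
#' @export
block_spec <- function(k1 = 8L, k2 = 8L) {
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (k1 < 1L || k2 < 1L) stop("block counts must be >= 1", call. = FALSE)
  structure(list(k1 = k1, k2 = k2), class = "block_spec")
}

block_bounds <- function(n, k) {
  k <- min(k, n)
  size <- n %/% k
  starts <- (0:(k - 1L)) * size + 1L
  ends <- c(starts[-1L] - 1L, n)  # remainder merged into the last block
  cbind(starts, ends)
}

# Per-channel block extrema; returns list(max, min) of k1 x k2 matrices.
block_extrema <- function(ch, blocks) {
  rb <- block_bounds(nrow(ch), blocks$k1)
  cb <- block_bounds(ncol(ch), blocks$k2)
  k1 <- nrow(rb); k2 <- nrow(cb)
  mx <- mn <- matrix(0, k1, k2)
  for (i in seq_len(k1)) {
    rows <- rb[i, 1L]:rb[i, 2L]
    for (j in seq_len(k2)) {
      blk <- ch[rows, cb[j, 1L]:cb[j, 2L]]
      mx[i, j] <- max(blk)
      mn[i, j] <- min(blk)
    }
  }
  list(max = mx, min = mn, k1 = k1, k2 = k2)
}

#' Colorfulness of an RGB image
#'
#' Moment statistic over the two opponent color spaces `alpha = R - G` and
#' `beta = 0.5 (R + G) - B` (on the 0-255 scale):
#' \deqn{0.02 \log\!\big(\sigma_\alpha^2 / |\mu_\alpha|^{0.2}\big)
#'            \log\!\big(\sigma_\beta^2 / |\mu_\beta|^{0.2}\big)}
#' Variances and means are guarded by `eps`, so constant images return the
#' finite floor value rather than `-Inf`.
#'
#' @param img RGB array `(y, x, 3)` in `[0, 1]`.
#' @param eps guard for logs/divisions, on the 0-255 scale.
#' @return scalar colorfulness score.
#' @export
colorfulness <- function(img, eps = METRIC_EPS) {
  img <- as_rgb_plane(img) * 255
  a <- img[, , 1L] - img[, , 2L]
  b <- 0.5 * (img[, , 1L] + img[, , 2L]) - img[, , 3L]
  va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
  if (va <= eps || vb <= eps)
    warning("near-constant opponent channel; colorfulness at the eps floor",
            call. = FALSE)
  term <- function(v, m) log(max(v, eps) / max(abs(m), eps)^0.2)
  0.02 * term(va, mean(a)) * term(vb, mean(b))
}

#' EME sharpness of an RGB image
#'
#' Weber-law measure of enhancement per channel,
#' \deqn{EME = \frac{2}{k_1 k_2} \sum_{k,l} \log\frac{I_{max,k,l}}{I_{min,k,l}}}
#' over the image blocks, combined across channels with the NTSC luminance
#' weights (0.299, 0.587, 0.114). Block minima are floored at `eps`.
#'
#' @inheritParams colorfulness
#' @param blocks a [block_spec()].
#' @return scalar sharpness score.
#' @export
sharpness_eme <- function(img, blocks = block_spec(), eps = METRIC_EPS) {
  img <- as_rgb_plane(img) * 255
  eme <- vapply(1:3, function(c) {
    be <- block_extrema(img[, , c], blocks)
    2 / (be$k1 * be$k2) * sum(log(pmax(be$max, eps) / pmax(be$min, eps)))
  }, numeric(1))
  sum(NTSC_WEIGHTS * eme)
}

#' AME contrast of an RGB image
#'
#' Michelson-law measure of enhancement per channel, as defined for this
#' family of metrics:
#' \deqn{AME = \frac{1}{k_1 k_2} \sum_k \Big(\sum_l
#'   \log\frac{I_{max}+I_{min}}{I_{max}-I_{min}}\Big)^{-0.5}}
#' (inner sum over column blocks, outer over row blocks), combined across
#' channels with the NTSC weights. Michelson contrast of a block grows as
#' `I_max - I_min` grows, the log ratio shrinks, and the `-0.5` power turns
#' the shrinkage into a larger score, so higher-contrast images score
#' higher. Denominators and the inner sums are floored at `eps`.
#'
#' @inheritParams sharpness_eme
#' @return scalar contrast score.
#' @export
contrast_ame <- function(img, blocks = block_spec(), eps = METRIC_EPS) {
  img <- as_rgb_plane(img) * 255
  ame <- vapply(1:3, function(c) {
    be <- block_extrema(img[, , c], blocks)
    inner <- log(pmax(be$max + be$min, eps) / pmax(be$max - be$min, eps))
    sum(pmax(rowSums(inner), eps)^-0.5) / (be$k1 * be$k2)
  }, numeric(1))
  sum(NTSC_WEIGHTS * ame)
}

#' Color quality enhancement (CQE) score
#'
#' Linear poll of the three component metrics,
#' `CQE = 0.4358 colorfulness + 0.1722 sharpness + 0.3920 contrast`,
#' a combination calibrated against human perception of color image
#' quality.
#'
#' @inheritParams sharpness_eme
#' @return an object of class `quality_scores` with fields `colorfulness`,
#'   `sharpness`, `contrast`, `cqe`, plus the weights and coefficients used.
#' @export
cqe <- function(img, blocks = block_spec(), eps = METRIC_EPS) {
  scores <- c(
    colorfulness = colorfulness(img, eps = eps),
    sharpness = sharpness_eme(img, blocks, eps = eps),
    contrast = contrast_ame(img, blocks, eps = eps)
  )
  structure(
    list(colorfulness = scores[["colorfulness"]],
         sharpness = scores[["sharpness"]],
         contrast = scores[["contrast"]],
         cqe = sum(CQE_COEF * scores),
         weights = NTSC_WEIGHTS, coefficients = CQE_COEF,
         blocks = blocks),
    class = "quality_scores"
  )
}

#' @export
print.quality_scores <- function(x, ...) {
  cat(sprintf(
    "colorfulness %.4f | sharpness %.4f | contrast %.4f | CQE %.4f\n",
    x$colorfulness, x$sharpness, x$contrast, x$cqe))
  invisible(x)
}

#' Spectral separation accuracy
#'
#' Quantifies how well a rendering separates three designated regions: the
#' mean RGB vector (colors in `[0, 1]`) of each region is treated as a
#' point in Euclidean color space, and the three pairwise distances are
#' summed and normalized by `3 * sqrt(2)` -- the maximum, attained when the
#' regions are pure red, green and blue. The score lies in `[0, 1]`.
#'
#' @param img RGB array `(y, x, 3)` (or `(1, y, x, 3)`) in `[0, 1]`.
#' @param regions list of three disjoint non-empty logical masks matching
#'   the image's spatial dimensions (e.g. the concentric-square masks
#'   returned by [build_shtc()]).
#' @return scalar separation accuracy in `[0, 1]`.
#' @export
separation_accuracy <- function(img, regions) {
  img <- as_rgb_plane(img)
  if (length(regions) != 3L) stop("`regions` must list three masks", call. = FALSE)
  means <- lapply(regions, function(m) {
    if (length(dim(m)) == 3L && dim(m)[1L] == 1L) m <- array(m[1L, , ], dim(m)[-1L])
    if (!any(m)) stop("empty region mask", call. = FALSE)
    vapply(1:3, function(c) mean(img[, , c][m]), numeric(1))
  })
  d12 <- sqrt(sum((means[[1L]] - means[[2L]])^2))
  d13 <- sqrt(sum((means[[1L]] - means[[3L]])^2))
  d23 <- sqrt(sum((means[[2L]] - means[[3L]])^2))
  (d12 + d13 + d23) / (3 * sqrt(2))
}
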