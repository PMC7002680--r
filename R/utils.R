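clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Convert HSV triples to RGB
#'
#' Vectorized hexcone transform. Unlike [grDevices::hsv()] this returns
#' numeric values without an 8-bit round trip, so map colors stay exact.
#'
#' @param h,s,v numeric vectors in `[0,1)` (hue) and `[0,1]`.
#' @return numeric matrix with columns `r`, `g`, `b` in `[0,1]`.
#' @keywords internal
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0 | i == 5, v, ifelse(i == 1, q, ifelse(i == 4, t, p)))
  g <- ifelse(i == 0, t, ifelse(i == 1 | i == 2, v, ifelse(i == 3, q, p)))
  b <- ifelse(i == 2, t, ifelse(i == 3 | i == 4, v, ifelse(i == 5, q, p)))
  cbind(r = r, g = g, b = b)
}

# Median of nine parallel vectors via Paeth's 19-exchange sorting network.
median_of_9 <- function(v) {
  sw <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]])
    v[[j]] <<- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo
  }
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  v[[5]]
}

#' 2D median filter with reflective edge padding
#'
#' @param m numeric matrix.
#' @param size odd window size (>= 3).
#' @return filtered matrix of the same dimensions.
#' @keywords internal
median_filter_2d <- function(m, size = 3L) {
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L)
    stop("`size` must be an odd integer >= 3", call. = FALSE)
  r <- (size - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 1L || nc < 1L) return(m)
  ri <- c(pmin(r:1, nr), seq_len(nr), pmax(nr - seq_len(r) + 1L, 1L))
  ci <- c(pmin(r:1, nc), seq_len(nc), pmax(nc - seq_len(r) + 1L, 1L))
  p <- m[ri, ci, drop = FALSE]
  shifts <- vector("list", size * size)
  idx <- 1L
  for (dx in 0:(size - 1L)) {
    for (dy in 0:(size - 1L)) {
      shifts[[idx]] <- as.vector(p[dy + seq_len(nr), dx + seq_len(nc)])
      idx <- idx + 1L
    }
  }
  med <- if (size == 3L) {
    median_of_9(shifts)
  } else {
    apply(do.call(cbind, shifts), 1L, stats::median.default)
  }
  matrix(med, nr, nc)
}
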