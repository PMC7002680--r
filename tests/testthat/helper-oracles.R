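# Straight-from-formula oracles, written independently of the
# implementation (explicit pixel/block loops, scalar arithmetic).

eps255 <- 1e-4 * 255

colorfulness_oracle <- function(img) {
  img <- img * 255
  a <- as.vector(img[, , 1] - img[, , 2])
  b <- as.vector(0.5 * (img[, , 1] + img[, , 2]) - img[, , 3])
  0.02 * log(max(var(a), eps255) / max(abs(mean(a)), eps255)^0.2) *
    log(max(var(b), eps255) / max(abs(mean(b)), eps255)^0.2)
}

blocks_oracle <- function(n, k) {
  k <- min(k, n); size <- n %/% k
  lapply(seq_len(k), function(i) {
    if (i < k) ((i - 1) * size + 1):(i * size) else ((k - 1) * size + 1):n
  })
}

eme_oracle <- function(img, k1, k2) {
  img <- img * 255
  per_ch <- sapply(1:3, function(ch) {
    m <- img[, , ch]
    rb <- blocks_oracle(nrow(m), k1); cb <- blocks_oracle(ncol(m), k2)
    tot <- 0
    for (ri in rb) for (ci in cb) {
      blk <- m[ri, ci]
      tot <- tot + log(max(max(blk), eps255) / max(min(blk), eps255))
    }
    2 / (length(rb) * length(cb)) * tot
  })
  sum(c(0.299, 0.587, 0.114) * per_ch)
}

ame_oracle <- function(img, k1, k2) {
  img <- img * 255
  per_ch <- sapply(1:3, function(ch) {
    m <- img[, , ch]
    rb <- blocks_oracle(nrow(m), k1); cb <- blocks_oracle(ncol(m), k2)
    tot <- 0
    for (ri in rb) {
      inner <- 0
      for (ci in cb) {
        blk <- m[ri, ci]
        inner <- inner + log(max(max(blk) + min(blk), eps255) /
                               max(max(blk) - min(blk), eps255))
      }
      tot <- tot + max(inner, eps255)^-0.5
    }
    tot / (length(rb) * length(cb))
  })
  sum(c(0.299, 0.587, 0.114) * per_ch)
}

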