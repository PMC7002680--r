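test_that("delta and flat spectra map to the canonical phasor positions", {
  N <- 32
  delta0 <- c(1, rep(0, N - 1))
  f <- spectral_phasor(uniform_cube(delta0), harmonic = 2)
  expect_equal(as.vector(f$g)[1], 1)
  expect_equal(as.vector(f$s)[1], 0)
  flat <- spectral_phasor(uniform_cube(rep(3.7, N)), harmonic = 2)
  expect_lt(max(abs(flat$g)), 1e-12)
  expect_lt(max(abs(flat$s)), 1e-12)
  # a delta at channel c lands on the unit circle at angle 2*pi*k*c/N
  for (k in 1:3) {
    for (cc in c(3, 10, 25)) {
      sp <- rep(0, N); sp[cc + 1] <- 2
      f <- spectral_phasor(uniform_cube(sp), harmonic = k)
      expect_equal(as.vector(f$g)[1], cos(2 * pi * k * cc / N), tolerance = 1e-12)
      expect_equal(as.vector(f$s)[1], sin(2 * pi * k * cc / N), tolerance = 1e-12)
    }
  }
})

test_that("the phasor transform is linear in the spectrum", {
  set.seed(42)
  N <- 32
  for (rep in 1:20) {
    S1 <- runif(N); S2 <- runif(N)
    a <- runif(1, 0, 3); b <- runif(1, 0, 3)
    p1 <- phasor_oracle(S1, 2); p2 <- phasor_oracle(S2, 2)
    w1 <- a * sum(S1) / (a * sum(S1) + b * sum(S2))
    expected <- w1 * p1 + (1 - w1) * p2
    f <- spectral_phasor(uniform_cube(a * S1 + b * S2, ny = 1, nx = 1), 2)
    expect_equal(c(f$g[1, 1, 1], f$s[1, 1, 1]), expected, tolerance = 1e-9)
  }
  # 50/50 mix of two deltas sits at the midpoint of the pure phasors
  sp <- rep(0, N); sp[c(4, 19)] <- 1
  f <- spectral_phasor(uniform_cube(sp), 2)
  mid <- (phasor_oracle(replace(rep(0, N), 4, 1), 2) +
          phasor_oracle(replace(rep(0, N), 19, 1), 2)) / 2
  expect_equal(c(f$g[1, 1, 1], f$s[1, 1, 1]), mid, tolerance = 1e-12)
})

test_that("nonnegative spectra stay inside the unit disc and match the oracle", {
  set.seed(1)
  cube <- spectral_image(array(rexp(2 * 5 * 6 * 16), c(2, 5, 6, 16)),
                         wavelength_axis(450, 10, 16))
  for (k in 1:3) {
    f <- spectral_phasor(cube, k)
    expect_true(all(f$g^2 + f$s^2 <= 1 + 1e-12))
    i <- c(2, 3, 4)  # spot-check one voxel against the direct formula
    expect_equal(c(f$g[2, 3, 4], f$s[2, 3, 4]),
                 phasor_oracle(cube$data[2, 3, 4, ], k, dl = 10),
                 tolerance = 1e-12)
  }
})

test_that("zero-intensity voxels are flagged null with the (0,0) sentinel", {
  sp <- runif(8)
  cube <- uniform_cube(sp, ny = 3, nx = 3, axis = wavelength_axis(450, 10, 8))
  cube$data[1, 2, 2, ] <- 0
  f <- spectral_phasor(cube, 2)
  expect_true(f$null[1, 2, 2])
  expect_equal(f$g[1, 2, 2], 0)
  expect_equal(sum(f$null), 1)
  zero <- spectral_image(array(0, c(1, 2, 2, 8)), wavelength_axis(450, 10, 8))
  expect_warning(fz <- spectral_phasor(zero, 2), "zero total intensity")
  expect_true(all(fz$null))
})

test_that("median filter matches a direct reflective-padding oracle", {
  refl <- function(v, n) {
    v <- ifelse(v < 1, 1 - v, v)
    ifelse(v > n, 2 * n - v + 1, v)
  }
  median_oracle <- function(m, size) {
    r <- (size - 1) / 2
    out <- m
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      out[i, j] <- stats::median(m[refl(i + (-r:r), nrow(m)),
                                   refl(j + (-r:r), ncol(m))])
    }
    out
  }
  set.seed(5)
  for (size in c(3, 5)) {
    m <- matrix(rnorm(12 * 9), 12, 9)
    expect_equal(seer:::median_filter_2d(m, size), median_oracle(m, size),
                 tolerance = 1e-15)
  }
})

test_that("phasor denoising is an identity at 0 cycles and removes outliers", {
  f <- fake_field(rep(0.5, 25), rep(0.2, 25))
  dim(f$g) <- dim(f$s) <- dim(f$intensity_sum) <- dim(f$null) <- c(1, 5, 5)
  expect_identical(phasor_denoise(f, cycles = 0), f)
  f$g[1, 3, 3] <- -0.9  # lone outlier in a constant field
  den <- phasor_denoise(f, cycles = 1, kernel = 3)
  expect_equal(den$g[1, 3, 3], 0.5)
  expect_error(phasor_denoise(f, kernel = 4), "odd")
  expect_error(phasor_denoise(f, cycles = 9), "between 0 and 5")
})

test_that("denoising shrinks phasor variance, keeps nulls and intensities", {
  set.seed(9)
  g <- array(0.4 + rnorm(400, sd = 0.05), c(1, 20, 20))
  s <- array(-0.1 + rnorm(400, sd = 0.05), c(1, 20, 20))
  inten <- array(runif(400), c(1, 20, 20))
  inten[1, 1, 1] <- 0
  f <- structure(list(g = g, s = s, intensity_sum = inten,
                      null = inten <= 0, harmonic = 2L),
                 class = "phasor_field")
  f$g[f$null] <- 0; f$s[f$null] <- 0
  den <- phasor_denoise(f, cycles = 1)
  expect_lt(stats::var(as.vector(den$g[!den$null])),
            stats::var(as.vector(f$g[!f$null])))
  expect_identical(den$null, f$null)
  expect_identical(den$intensity_sum, f$intensity_sum)
  expect_equal(den$g[1, 1, 1], 0)
})

test_that("phasor histogram conserves voxels and localizes pure spectra", {
  sp <- runif(16)
  cube <- uniform_cube(sp, ny = 6, nx = 5, axis = wavelength_axis(450, 10, 16))
  h <- phasor_histogram(spectral_phasor(cube, 2), n_bins = 64)
  expect_equal(sum(h$counts > 0), 1)  # one spectrum, one bin
  expect_equal(max(h$counts), 30)
  # half/half two-spectra image: two bins with the region sizes
  sp2 <- rev(sp)
  cube$data[1, , 1:2, ] <- rep(sp2, each = 12)
  h2 <- phasor_histogram(spectral_phasor(cube, 2), n_bins = 64)
  expect_equal(sort(h2$counts[h2$counts > 0]), c(12, 18))
  # conservation on a random cube with some null voxels
  set.seed(3)
  arr <- array(rexp(5 * 6 * 16), c(5, 6, 16))
  arr[2, 2, ] <- 0
  f <- spectral_phasor(spectral_image(arr, wavelength_axis(450, 10, 16)), 2)
  h3 <- phasor_histogram(f, 32)
  expect_equal(h3$total_count, sum(!f$null))
  expect_equal(sum(is.na(h3$bin_index)), sum(f$null))
  expect_error(phasor_histogram(f, 1), "n_bins")
})

test_that("polar conversion is quadrant-aware on [0, 2*pi)", {
  expect_equal(to_polar(1, 0), list(r = 1, theta = 0))
  expect_equal(to_polar(0, -1)$theta, 3 * pi / 2)
  p <- to_polar(-0.3, 0.4)
  expect_equal(p$r, 0.5)
  expect_equal(p$theta, pi - atan(4 / 3))
  expect_equal(to_polar(0, 0), list(r = 0, theta = 0))
  set.seed(2)
  th <- runif(50, 0, 2 * pi); rr <- runif(50)
  pp <- to_polar(rr * cos(th), rr * sin(th))
  expect_equal(pp$r, rr)
  expect_equal(pp$theta, th)
})
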