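test_that("apex computation follows the histogram maximum and center of mass", {
  n <- 5  # bin centers at -0.8, -0.4, 0, 0.4, 0.8
  FF <- matrix(0, n, n)
  FF[4, 3] <- 7  # single bin at (g, s) = (0.4, 0)
  h <- fake_hist(FF)
  expect_equal(unclass(compute_apex(h, "max"))[c("g", "s")], list(g = 0.4, s = 0))
  expect_equal(unclass(compute_apex(h, "mass"))[c("g", "s")], list(g = 0.4, s = 0))
  # two bins, counts 3 at (0, 0.4) and 1 at (0.4, 0): mass apex (0.1, 0.3)
  FF2 <- matrix(0, n, n); FF2[3, 4] <- 3; FF2[4, 3] <- 1
  h2 <- fake_hist(FF2)
  a2 <- compute_apex(h2, "mass")
  expect_equal(c(a2$g, a2$s), c(0.1, 0.3), tolerance = 1e-12)
  expect_equal(c(compute_apex(h2, "max")$g, compute_apex(h2, "max")$s), c(0, 0.4))
  # histogram symmetric about the origin: mass apex at the origin
  FF3 <- matrix(0, n, n); FF3[2, 2] <- 4; FF3[4, 4] <- 4
  a3 <- compute_apex(fake_hist(FF3), "mass")
  expect_equal(c(a3$g, a3$s), c(0, 0), tolerance = 1e-12)
  expect_error(compute_apex(fake_hist(matrix(0, n, n))), "empty")
})

test_that("scale transform warps the bounding ellipse onto the unit circle", {
  # full [-1,1]^2 box: identity on random interior points
  box <- make_bbox(-1, 1, -1, 1)
  set.seed(4)
  g <- runif(100, -0.7, 0.7); s <- runif(100, -0.7, 0.7)
  tr <- scale_transform(g, s, box)
  expect_equal(tr$g, g, tolerance = 1e-12)
  expect_equal(tr$s, s, tolerance = 1e-12)
  # centered half-size box: ellipse boundary (r_i = 0.5) -> r_o = 1
  half <- make_bbox(-0.5, 0.5, -0.5, 0.5)
  th <- runif(20, 0, 2 * pi)
  expect_equal(scale_transform(0.5 * cos(th), 0.5 * sin(th), half)$r,
               rep(1, 20), tolerance = 1e-12)
  expect_equal(scale_transform(0, 0, half)$r, 0)
  # general off-center boxes: parametrized ellipse boundary maps to r_o = 1
  for (rep in 1:10) {
    ctr <- runif(2, -0.3, 0.3); ab <- runif(2, 0.1, 0.5)
    bx <- make_bbox(ctr[1] - ab[1], ctr[1] + ab[1], ctr[2] - ab[2], ctr[2] + ab[2])
    tt <- runif(15, 0, 2 * pi)
    tr <- scale_transform(ctr[1] + ab[1] * cos(tt), ctr[2] + ab[2] * sin(tt), bx)
    expect_equal(tr$r, rep(1, 15), tolerance = 1e-9)
  }
  expect_error(make_bbox(0, 0, -1, 1), "degenerate")
})

test_that("morph transform fixes the unit circle and recovers the standard map", {
  set.seed(6)
  th <- runif(40, 0, 2 * pi)
  rr <- sqrt(runif(40))
  g <- rr * cos(th); s <- rr * sin(th)
  # apex at the origin: identity on the disc
  tr0 <- morph_transform(g, s, list(g = 0, s = 0))
  expect_equal(tr0$g, g, tolerance = 1e-9)
  expect_equal(tr0$s, s, tolerance = 1e-9)
  for (apex in list(list(g = 0.3, s = 0), list(g = -0.2, s = 0.45))) {
    # unit-circle points are fixed points for any apex
    trc <- morph_transform(cos(th), sin(th), apex)
    expect_equal(trc$g, cos(th), tolerance = 1e-9)
    expect_equal(trc$s, sin(th), tolerance = 1e-9)
    # the apex itself maps to the map origin
    tra <- morph_transform(apex$g, apex$s, apex)
    expect_equal(c(tra$g, tra$s), c(0, 0))
    # interior points stay inside, with alpha in [0, 1)
    tri <- morph_transform(g, s, apex)
    expect_true(all(tri$r <= 1 + 1e-9))
    expect_true(all(tri$alpha >= 0 & tri$alpha < 1))
    # solutions satisfy the shifted-cone identity exactly
    resid <- (g - tri$alpha * apex$g)^2 + (s - tri$alpha * apex$s)^2 -
      (1 - tri$alpha)^2
    expect_lt(max(abs(resid)), 1e-9)
  }
  expect_error(morph_transform(0.1, 0.1, list(g = 0.8, s = 0.7)), "apex")
})

test_that("LUTs honor mode semantics", {
  sp <- runif(16)
  cube <- uniform_cube(sp, ny = 8, nx = 8, axis = wavelength_axis(450, 10, 16))
  set.seed(12)
  cube$data <- cube$data * array(runif(prod(dim(cube$data)[1:3]), 0.5, 1),
                                 dim(cube$data))  # intensity variation only
  f <- spectral_phasor(cube, 2)
  h <- phasor_histogram(f, 64)
  # standard LUT is dataset-independent
  lut_a <- build_lut("gradient_descent", "standard", hist = h)
  lut_b <- build_lut("gradient_descent", "standard", n_bins = 64)
  expect_identical(lut_a$rgb, lut_b$rgb)
  # occupied bins are colored (non-black) in standard mode
  occ <- which(h$counts > 0)
  lutm <- matrix(lut_a$rgb, 64 * 64, 3)
  expect_true(all(rowSums(lutm[occ, , drop = FALSE]) > 0))
  # morph_mass on an origin-symmetric histogram collapses to the standard map
  n <- 9
  FF <- matrix(0, n, n); FF[3, 3] <- 5; FF[7, 7] <- 5
  hs <- fake_hist(FF)
  expect_equal(build_lut("angular", "morph_mass", hist = hs)$rgb,
               build_lut("angular", "standard", n_bins = n)$rgb,
               tolerance = 1e-9)
  expect_error(build_lut("angular", "morph_max", n_bins = 32), "histogram")
})

test_that("scale mode spreads hues for a compact off-center cluster", {
  # compact blob of phasors away from the origin
  set.seed(21)
  g <- 0.45 + runif(300, -0.05, 0.05)
  s <- -0.3 + runif(300, -0.05, 0.05)
  f <- fake_field(g, s)
  h <- phasor_histogram(f, 128)
  hue_of <- function(lut) {
    lutm <- matrix(lut$rgb, 128 * 128, 3)
    occ <- unique(h$bin_index[!is.na(h$bin_index)])
    cols <- lutm[occ, , drop = FALSE]
    grDevices::rgb2hsv(t(cols * 255))[1, ]
  }
  circ_var <- function(hue) 1 - sqrt(mean(cos(2 * pi * hue))^2 +
                                     mean(sin(2 * pi * hue))^2)
  v_std <- circ_var(hue_of(build_lut("angular", "standard", hist = h)))
  v_scl <- circ_var(hue_of(build_lut("angular", "scale", hist = h)))
  expect_gt(v_scl, v_std)
  # every occupied bin stays inside the wrapped map (non-black)
  lut_s <- build_lut("angular", "scale", hist = h)
  lutm <- matrix(lut_s$rgb, 128 * 128, 3)
  occ <- unique(h$bin_index[!is.na(h$bin_index)])
  expect_true(all(rowSums(lutm[occ, , drop = FALSE]) > 0))
})

test_that("the enclosing box wraps every occupied bin inside the ellipse", {
  set.seed(33)
  # three separated clusters, one at the box corner
  g <- c(rnorm(80, -0.5, 0.03), rnorm(80, 0.2, 0.03), rnorm(80, 0.6, 0.03))
  s <- c(rnorm(80, -0.5, 0.03), rnorm(80, 0.5, 0.03), rnorm(80, 0.4, 0.03))
  h <- phasor_histogram(fake_field(g, s), 128)
  box <- enclosing_bbox(h)
  occ <- which(h$counts > 0, arr.ind = TRUE)
  r <- scale_transform(h$centers[occ[, 1]], h$centers[occ[, 2]], box)$r
  expect_true(all(r <= 1 + 1e-9))
  expect_equal(max(r), 1, tolerance = 1e-9)  # smallest such dilation
})
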