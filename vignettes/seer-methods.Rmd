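---
title: "Phasor-based color rendering of hyperspectral fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor-based color rendering of hyperspectral fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seer)
```

## The problem

A spectral confocal or multiphoton microscope records, for every pixel, an
emission spectrum over tens of wavelength channels (typically 32 channels
from 410.5 nm at 8.9 nm bandwidth). Displaying such a cube as an RGB image
requires compressing the wavelength axis to three numbers per pixel, and
naive compressions (summing channels under fixed R/G/B weights, or coloring
by the peak channel) discard most of the spectral contrast -- especially
when fluorophores or autofluorescent species overlap heavily in emission.

`seer` implements SEER (Spectrally Encoded Enhanced Representations): the
per-pixel spectrum is reduced to its spectral phasor -- the pair of
normalized Fourier coefficients

$$g = \frac{\sum_{c=0}^{N-1} I(\lambda_c)\cos(2\pi k c/N)\,\Delta\lambda}
           {\sum_c I(\lambda_c)\,\Delta\lambda},\qquad
  s = \frac{\sum_{c=0}^{N-1} I(\lambda_c)\sin(2\pi k c/N)\,\Delta\lambda}
           {\sum_c I(\lambda_c)\,\Delta\lambda}$$

at harmonic $k$ -- and color is assigned by where the pixel lands on the
phasor plane. The transform is linear in the spectrum, normalizes away
total intensity, and maps every nonnegative spectrum inside the unit disc;
a flat spectrum sits exactly at the origin. Spectral differences far below
what the eye can pick out of a TrueColor rendering become large
displacements in phasor space, which the reference maps below turn into
large hue differences.

## Pipeline and its assumptions

1. **Phasor transform** (`spectral_phasor()`), harmonic $k$ selectable 1-3,
   default 2. The Fourier argument uses the channel *index* $c = 0..N-1$,
   not the physical wavelength; this is what makes the flat spectrum map to
   the origin and lets harmonic $k$ span $k$ full periods across the
   detector. Pixels with zero integrated intensity have no defined phasor;
   they are flagged null and render black throughout.
2. **Phasor-space denoising** (`phasor_denoise()`): a median filter applied
   to the $g$ and $s$ images independently, per z-slice, 0-5 cycles
   (default 1 cycle, 3x3 window, reflective edge padding). Filtering the
   phasor coordinates instead of the raw channels shrinks the photon-noise
   scatter of the phasor cloud without moving any pixel or changing any
   intensity -- the operation is spatially lossless. Near boundaries
   between spectrally distinct regions the filter mixes neighborhoods; our
   region-statistics tests therefore erode masks by the filter radius.
3. **Histogram** (`phasor_histogram()`): the non-null phasors are binned on
   an `n_bins` x `n_bins` grid over $[-1,1]^2$ (default 256, a resolution
   at which LUT quantization is invisible at 8-bit display depth).
4. **Reference map + mode** (`build_lut()`): every histogram bin center is
   assigned a color (below), optionally after an adaptive coordinate
   transform (scale or morph mode).
5. **Rendering** (`apply_lut()`): each pixel takes its bin's color, either
   as a pure RGB mask (`flat`) or modulated by normalized integrated
   intensity (`scaled`).

## Reference maps

With polar phasor coordinates $r = \sqrt{g^2+s^2}$ and the quadrant-aware
angle $\theta \in [0, 2\pi)$:

| map | hue | saturation | value |
|---|---|---|---|
| gradient descent | $\theta/2\pi$ | 1 | $1 - 0.85\,r$ |
| gradient ascent | $\theta/2\pi$ | 1 | $r$ |
| angular | $\theta/2\pi$ | 1 | 1 |
| radial | jet colormap in $r$ | -- | -- |

Anything outside the $r = 1$ boundary is black. The jet ramp is pinned to
fixed numeric anchors so results do not depend on a plotting library. Two
printed conventions in the source material required a decision: the
published HSV table lists hue = 0 for the ascent and angular maps, while
the accompanying prose and color wheels make hue a function of angle for
all three HSV maps; we follow the prose. Likewise the polar-angle formulas
are printed as plain ratios ($s/g$); only the quadrant-aware arctangent
produces an angle, so that is what is implemented. At $r = 0$, where
$\theta$ is undefined, hue defaults to 0.

The **tensor map** (`tensor_gradient()` + `tensor_map_render()`) colors
each pixel by the normalized magnitude of the gradient of histogram
*counts* at its bin (second-order central differences, unit bin spacing,
one-sided stencils at the grid edge where the central stencil does not
exist). Dense cluster cores and sparse cluster fringes sit at different
gradient levels, so the rendering acts as a spectral edge detector: rare
spectra stand out. On a noiseless synthetic chart every spectrum collapses
to one isolated bin and all occupied bins have zero gradient; the map is
informative exactly when clusters have spatial extent (i.e. on real or
noisy data).

## Contrast modes

**Scale mode** stretches spectral contrast by warping the reference map so
its unit circle becomes an ellipse adapted to the data: coordinates are
recentred on the bounding-box center of the occupied histogram bins and
radii rescaled by the local ellipse radius, so the ellipse boundary maps to
the map edge ($r_o = 1$) and the box center to the map origin. The printed
construction (largest ellipse inscribed in the bounding box) clips any
cluster sitting near a box *corner* to black, which contradicts the stated
intent that the warped map wrap around all phasor points; when the box is
derived automatically we therefore dilate both semi-axes by the smallest
common factor that brings every occupied bin inside the ellipse
(`enclosing_bbox()`). A user-supplied box (`make_bbox()`) is used verbatim,
e.g. to hold the palette constant across samples.

**Morph mode** keeps the unit circle anchored and moves the map's center
(the *apex*) to either the histogram maximum (`morph_max`) or the
count-weighted centroid (`morph_mass`). Geometrically the standard map is a
right cone over the unit disc viewed from above; shifting the apex to
$A$ produces an oblique cone whose horizontal sections project to circles
of radius $1-\alpha$ centered at $\alpha A$. For a pixel at $p$ the section
parameter solves the quadratic
$(p - \alpha A)^2 = (1-\alpha)^2$; we take the root in $[0,1)$, and the
smaller one if both qualify (closest to the standard map). Unit-circle
points get $\alpha = 0$ and are fixed; $p = A$ is special-cased to the map
origin (the quadratic degenerates there); apex $(0,0)$ recovers the
standard map identically. Scale and morph are not composed: the four modes
are exclusive.

## Baseline renderings

For comparison the package implements the two standard compressions:

* `truecolor_gaussian()`: each output channel weights the spectrum with a
  Gaussian similarity kernel $K_i = e^{-(x_i - x')^2/2\sigma^2}$ centered
  at 650/510/470 nm for R/G/B. The kernel deviation is not fixed by the
  published description; we default to $\sigma = 50$ nm, which spans 5-6
  detector channels and reproduces the smooth color blending of reference
  renderings. Each kernel is normalized to unit sum over channels ("the
  normalized weight" is not given a formula in the source description;
  unit-sum is the choice documented here), and the image is scaled by its
  global maximum. `adaptive_centers()` re-derives the centers from the
  dataset: the blue/red centers sit where the normalized average spectrum
  crosses a chosen fraction (10/20/30%) on the left/right, green halfway
  between.
* `peak_wavelength_rgb()`: each pixel takes the visible-spectrum color
  (piecewise-linear wavelength-to-RGB conversion, `wavelength_to_rgb()`)
  of its argmax channel, ties broken toward the lower wavelength.

`mip()` projects RGB z-stacks by maximal luminance so that projected
pixels keep physically co-located colors rather than mixing channels
across depths.

## Quality metrics

`colorfulness()`, `sharpness_eme()`, `contrast_ame()` and their linear
poll `cqe()` (coefficients 0.4358/0.1722/0.3920, NTSC channel weights
0.299/0.587/0.114) are computed on the 0-255 scale with natural
logarithms; neither the scale, the log base, nor the block counts are
fixed by the published definitions, so all are parameters, with defaults
0-255 / natural log / 8 x 8 blocks, and every log or division is guarded
by eps = 1e-4 (on the unit scale). AME is implemented exactly as printed
-- the inner block sum is raised to the power $-0.5$ -- with the inner sum
floored at eps so constant images return a finite sentinel rather than
infinity. These choices shift absolute metric values but cancel in the
relative comparisons the metrics are used for.

`separation_accuracy()` measures how distinctly a rendering separates
three designated regions: the pairwise Euclidean distances between the
region-mean RGB vectors (colors in $[0,1]$) are summed and divided by
$3\sqrt2$, the maximum attained exactly when the regions are pure red,
green and blue. Region means (rather than per-pixel pairings) make that
normalization exact.

## The simulated test chart

`build_shtc()` generates the synthetic ground-truth target: a 300 x 300 x
32 cube arranged as a 3 x 3 grid of 100-px cells, each holding three
concentric square regions (outer ring 25 px, middle ring 15 px, center
square 20 x 20 px -- the published layout shows but does not dimension
them) carrying three spectra S1/S2/S3. The real chart was built from
acquired CFP/YFP/RFP emission spectra, which are not tabulated anywhere we
can read them from; the generator substitutes Gaussian surrogates (peaks
475/527/580 nm, width sigma = 15 nm -- typical widths for these
fluorescent proteins) and exposes every parameter. Per cell, the S1/S3
peaks are shifted relative to S2 in multiples of the 8.9 nm channel
bandwidth (center cell unshifted), giving a graded-overlap chart;
`shtc_overlap_chart(d1, d2)` builds the uniform charts used in benchmarks,
with maxima at $527 - d_1$, $527$, $527 + d_2$ nm.

`add_noise()` emulates the microscope's counting statistics: channel
intensities are scaled so the cube maximum corresponds to `photon_scale`
expected photons, Poisson-resampled, and summed with zero-mean Gaussian
read noise (clipped at zero). A seed is mandatory; there is no hidden RNG
state. What the generator does *not* emulate: detector spectral response
curves, bleed-through matrices, scattering, or the non-Gaussian tails of
real emission spectra -- so passing benchmarks demonstrate the pipeline's
behavior under controlled overlap and SNR, not performance on any
particular instrument.

## The separation benchmark

`separation_benchmark()` reproduces the package's headline comparison: on
uniform-overlap charts with Poisson (photon_scale 100) plus read noise
(sd 2), rendered with the gradient-descent map in scale mode (k = 2, one
denoise cycle) versus Gaussian-kernel TrueColor (650/510/470, sigma 50),
it reports the mean ratio of separation accuracies over seeded replicates.
Two regimes are exercised: maxima offsets (0, 8.9) nm -- all three peaks
within one channel bandwidth -- and (17.8, 35.6) nm.

One protocol point matters and is deliberate: both renderings are
normalized to their own maximum channel value before scoring
(`normalize_display = TRUE`). The TrueColor baseline is max-normalized by
construction, while the SEER flat mask is not -- the gradient-descent
value ramp caps peripheral colors near 0.15-0.4 -- so comparing the raw
mask against the normalized baseline would measure overall brightness
rather than color separation, and no map choice could recover the known
fold-improvements under that asymmetry. Scoring both images on the full
display range (exactly what any 8-bit display pipeline does) keeps the
statistic about chromatic separation. At these settings the benchmark
yields mean ratios well above 1 in both regimes; the acceptance script
(`scripts/acceptance.R`) recomputes them from scratch over 10 seeds.

Problem sizes throughout the test-suite were chosen for tight feedback
loops: full 300-px charts for the benchmark itself, 60-120-px charts for
structural and convergence checks, 10 seeds per benchmark regime.

## Known limitations

* Cube input is multichannel TIFF (ImageJ-hyperstack dialect, channels as
  planes) or in-memory arrays; vendor formats and HDF5 containers must be
  converted upstream. TIFF carries no wavelength metadata, so the default
  32-channel/410.5/8.9 axis is attached (with a warning) when none is
  supplied.
* The printed wavelength range 410.5-694.9 nm is not exactly representable
  with 32 x 8.9 nm bins (410.5 + 32 x 8.9 = 695.3); we keep the printed
  start and bandwidth and treat the printed endpoint as rounded.
* Harmonics above 3 and composed modes (scale + morph) are intentionally
  unsupported; time-lapse LUT animation is out of scope, though per-frame
  recomputation works.
* The no-reference metrics are implemented for relative comparisons;
  absolute values depend on the documented scale/log/block conventions.
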