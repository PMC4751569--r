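---
title: "Mass-per-unit-length densitometry from dark-field TEM: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-per-unit-length densitometry from dark-field TEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilMPL)
```

## The measurement model

Tilted-beam dark-field TEM collects only scattered electrons, and for thin
unstained specimens the recorded intensity is, to a good approximation,
proportional to the projected mass in each pixel. The proportionality
constant is unknown and varies between exposures, so absolute mass cannot
be read off an image. It cancels, however, in a ratio taken *within one
image* against an internal standard of known mass per unit length (MPL).
Tobacco mosaic virus is the classic choice: a rigid rod of MPL
K = 131 kDa/nm.

For each 1-px axial step $s$ along a selected filament segment, the
package sums intensity over a one-pixel-thick band of width $w$
perpendicular to the axis ($I(s)$) and over two flanking background bands
of the same width ($B_L(s)$, $B_R(s)$), and forms

$$\mathrm{MPL}(s) \;=\; \frac{I(s) - \tfrac{1}{2}\left(B_L(s)+B_R(s)\right)}
                             {C_\mathrm{std}} \times K ,$$

where $C_\mathrm{std}$ is the mean corrected intensity over every slice
of every standard selection in the same image. The model's assumptions,
and where they bite:

- **Linearity**: detector response is linear in mass. Averaging two
  flanking bands removes a constant or laterally linear background;
  curvature of the background across the filament is not removed.
- **Same illumination**: standards and fibrils must share one exposure.
  The API deliberately takes a single image per measurement run; there is
  no cross-image calibration transfer.
- **Full coverage**: the band must be wider than the filament. Undersized
  $w$ truncates the mass integral and biases MPL *down*; this is the
  dominant user-controllable error and the reason for the width sweep
  below.
- **No mass-loss correction**: beam-induced mass loss and dynamic
  scattering corrections (standard in dedicated STEM software) are out of
  scope; they fold into the internal standard only to the extent that the
  standard suffers them equally.

## Geometry and sampling conventions

Coordinates are 0-based with x = column, y = row, origin top-left, pixel
centers at integers. A selection is a straight segment $(x_0,y_0) \to
(x_1,y_1)$ with band width $w \ge 1$ px. The axial unit vector $u$ is
stepped exactly 1 px at a time for $s = 0, \dots, \lfloor L \rfloor$ (the
fractional remainder of $L$ is not sampled); the band direction is $u$
rotated $+90^\circ$ in image coordinates. Within a slice, samples sit at
lateral offsets $-(n_w-1)/2, \dots, (n_w-1)/2$ with $n_w =
\mathrm{round}(w)$, and the background bands are displaced laterally by
$\pm(n_w + \mathrm{gap})$.

Numerical choices, made once and used everywhere:

- **Bilinear interpolation** for off-grid samples. It is the standard
  compromise for 1-px profile work, and it is *exactly* testable: at
  integer geometry every band sum equals a direct pixel sum, which the
  test suite asserts bit-for-bit against a brute-force oracle.
- **Border handling**: a slice with *any* of its $3 n_w$ sample points
  outside the image is discarded and counted (`n_dropped`), never
  zero-filled — padding would bias sums. If every slice drops, the run
  fails with the selection named.
- **`gap` = 2 px** between the signal band edge and each background band.
  The clearance protects against filament-edge bleed. One subtle
  consequence, documented because the test suite pins it: for an
  even band width the innermost background sample sits at a half-integer
  offset and bilinearly clips the bar edge once $w + \mathrm{gap}$ is
  small enough. On the 25-px validation bar, $w = 20$, gap 2 yields
  $19.5/25$ of nominal (78), not the naive coverage fraction $20/25$
  (80); with gap 3 the bands clear the bar and the coverage fraction is
  exact.
- **Left/right naming** of background bands follows the rotated normal
  and is immaterial: only their mean enters the formula.
- **8-bit export** rounds half-away-from-zero and clips to [0, 255].
  Clipping a black background truncates the noise floor at 0, inflating
  measured background by $\sigma/\sqrt{2\pi}$ per pixel and depressing
  MPL by a few percent at $\sigma = 25$ — the test suite asserts the
  direction of this bias, and the synthetic pipeline therefore defaults
  to float TIFF.

## Calibration and aggregation

`calibrate()` pools *slices*, not per-standard means, so longer standards
carry proportionally more weight; `per_standard_mean = TRUE` switches to
equal weight per standard molecule. A calibration with
$C_\mathrm{std} \le 0$ (standard darker than background) is rejected —
it indicates a beam-tilt or selection error.

The headline number is the **pooled mean** over every 1-px slice of every
fibril; fibril-level statistics (mean of per-fibril means, their SD and
SEM) are emitted alongside because published "mean ± x" values are often
ambiguous between the two conventions. Neither is guessed: the summary
file names pooled SD, fibril SD, and fibril SEM explicitly. Negative
per-slice MPLs are kept in all means; clipping them would bias noisy data
upward. Curved fibrils are measured as chains of short straight segments
sharing a fibril id (label text before `":"`); the chord-vs-arc error of
this approximation stays below 3% for segment lengths up to about 1/8 of
the bend's period, which the curved-phantom test verifies by simulation.

## The fluctuation statistic

Measurement uncertainty is estimated from consecutive differences one
pixel apart along the axis: `sd_bg_diff` is the SD of $B(s) - B(s+1)$
with $B = (B_L + B_R)/2$, and `sd_fibril_diff` the same statistic on the
corrected signal $I - B$. Pairs are formed only between consecutive
retained slice indices within one selection — never across selections or
across gaps left by dropped slices. Differencing removes slow trends, so
the background statistic isolates shot-like noise; if the fibril-side
statistic exceeds it, the excess variance comes from the fibril itself
(structural heterogeneity along the axis, standard-to-standard
variability, mass loss during exposure). Because "the SD of the
background distribution" could also mean the about-mean SD of the series,
both conventions are computed; the difference convention is primary. On
a pure-noise phantom sampled at integer geometry (odd $w$), slices are
independent and the statistic has the closed form $\sigma\sqrt{w}$; the
acceptance suite checks the pipeline against a $10^5$-pair Monte-Carlo
oracle of the same construction within 2%.

## What the synthetic generator does and does not emulate

`generate_phantom()` renders the canonical validation image: vertical
bars of exact integer width (default 25 px) at intensities 131 (standing
in for TMV), 100, and 200 on a black 512×512 field, with i.i.d. Gaussian
noise of SD 25 added in floating point. Defaults not fixed by that
layout were chosen once: the 512² canvas and bar abscissae 100/256/412
keep every bar's background bands clear of its neighbours (enforced by a
spec-time overlap check), selections are inset 5 px from the edges, and
the default selection width is 30 px (comfortably above the 25-px bars).
Replicate $r$ of a sweep uses seed $\mathrm{seed} + r - 1$, so sweeps are
reproducible. Optional extras emulate specific effects: sinusoidal
along-axis intensity modulation (heterogeneity for the fluctuation
statistic), a 1-px selection offset (user mis-centering), 8-bit clipping
(the historical 8-bit workflow), and a sinusoidal-axis ribbon with
constant mass per unit arc length (curved fibrils).

The generator deliberately does **not** model dark-field image formation:
no detector MTF or shot-noise scaling with signal, no beam-tilt
anisotropy, no carbon-film texture (real background noise is spatially
correlated; the phantom's is white), no helical intensity repeat along
fibrils, and no standard-to-standard intensity variability. A green test
on the phantom therefore establishes the *estimator's* correctness —
geometry, interpolation, background subtraction, calibration algebra,
aggregation — and its unbiasedness under zero-mean white noise. It does
not establish accuracy on real micrographs, where staining, drying
artefacts, salt contamination and mass loss dominate; on real data the
method is a working estimate of order ±15%.

## Width robustness

`width_sweep()` reproduces the classic validation experiment: measure a
bar of true width 25 px with band widths 20–40 px. Below the true width
the recovered MPL rises monotonically (each extra pixel of band adds
truncated mass); at and above it, the noiseless sweep is exactly flat at
nominal for centered selections, and flat from $w = 27$ when the
selection is mis-centered by 1 px — the practical rule being to choose
$w$ comfortably above the filament width, since excess width costs only
noise, not bias. The swept width is applied to the *target* bar only;
sweeping the standard too would cancel the very bias the experiment
demonstrates.

## Known limitations

- Straight segments only; curvature is handled by chaining, not by
  spline fits, and there is no sub-pixel auto-centering on the ridge.
- Background bands are tied to the signal band's width and a fixed gap;
  strongly curved backgrounds or close-packed filaments violate the
  flanking-band assumption (the overlap margin in the phantom spec
  exists precisely because neighbouring structures contaminate
  background bands).
- One image per run; no batch averaging across micrographs.
- TIFF support is a minimal baseline codec (grayscale, strips,
  none/deflate); tiled, predictor-compressed, or planar files from
  exotic writers are out of scope, as are MRC/DM3/DM4 microscope formats
  — convert upstream.
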