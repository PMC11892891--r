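---
title: "Lossy compression of rotation-series diffraction images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lossy compression of rotation-series diffraction images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxsqueeze)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the choices made where the design was
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The quantities being traded off

A compression ratio is the quotient of the original image size over the
compressed size, in comparable units. For most diffraction images a
lossless codec cannot do much better than the CBF byte-offset scheme —
on 4-byte-per-pixel data whose successive deltas fit one byte it
approaches exactly 4:1 — so byte-offset payload size is a practical proxy
for the entropy limit. All further compression must discard information.
The **extra compression ratio**

> ECR = (byte-offset payload bytes of the as-collected stack) / (lossy payload bytes)

measures compression achieved *beyond* that lossless baseline, and
satisfies `ECR x baseline_ratio = total_ratio` exactly because all three
are ratios of the same payload byte counts. Sizes here are payload-only:
container headers and the bit-packed mask are excluded (and reported
separately as `container_bytes`), which makes the 4:1 flat-plane figure
exactly recoverable and keeps ratios container-independent.

What the archive must not lose is the Bragg signal, and the weak
reflections are the canary: anomalous-phasing experiments live off
intensity differences far smaller than the intensities themselves.
The package therefore pairs every codec with impact metrics calibrated on
synthetic scenes whose ground truth is known exactly.

## 2. The byte-offset codec

Values are delta-coded against the previous value (initial previous 0).
A delta in [-127, 127] is one signed byte; otherwise the marker `0x80` is
followed by a signed 16-bit little-endian delta; the nested markers
`0x8000` and `0x80000000` escalate to 32- and 64-bit deltas. Note the
worst case is 15 bytes per value (1 + 2 + 4 + 8), reached only when every
delta exceeds 31 bits. Frames are encoded as row-major rasters with the
gap sentinel substituted first, because the baseline must measure the
same stream a detector control unit would store; sentinels are large
constants surrounded by small counts, so they cost a handful of escapes
per gap row and nothing more.

## 3. The H-transform codec

### Transform

The forward transform recursively replaces each 2x2 block
`[[p00, p01], [p10, p11]]` by

```
h0 = p00 + p01 + p10 + p11      (sum; feeds the next level)
hx = (p10 + p11) - (p00 + p01)  (row difference)
hy = (p01 + p11) - (p00 + p10)  (column difference)
hc = p11 - p10 - p01 + p00      (cross term)
```

No division is performed at any level — the divisions are deferred
entirely to the inverse, where `(h0 +/- hx +/- hy +/- hc) / 4` is exact
on unquantized integer input. This gives bit-exact invertibility at the
cost of coefficients that grow with level; they are carried as doubles,
exact far beyond the 32-bit detector range. Planes are padded to the next
power-of-two square by **edge replication** (constant padding would
inject step edges straight into the detail bands) and cropped on decode.

### Quantization scale

A detail coefficient produced at pyramid level `l` (0 = finest) is
quantized by `round_half_away_from_zero(c / (scale * 2^l))`. The factor
`2^l` restores the Haar normalization that the deferred division removed:
an error `e` in a level-`l` coefficient spreads over `4^(l+1)` pixels at
amplitude `e / 4^(l+1)`, so with step `scale * 2^l` every level
contributes the same mean-squared reconstruction error — the behaviour of
the astronomy codec's uniform step on normalized coefficients. Scales 0
and 1 change nothing (lossless mode). The DC term is never quantized, so
the reconstruction preserves the total count and hence the background
mean; rounding half away from zero keeps the quantizer symmetric around
zero for the signed detail bands.

### Entropy stage and bitstream

Quantized coefficients are serialized as a zigzag-varint byte stream and
deflated (`memCompress`). This is deliberately *not* the astronomy
program's quadtree bit-plane bitstream: that tool was always used as a
black box, and what matters for the trade-off study is the transform and
scale semantics plus a measurable, exactly-round-tripping payload. The
dialect is recorded as `codec_variant_id = "hconv1-zzvarint-deflate"` in
every blob and container, and decoders refuse unknown variants rather
than guess. No decode-time smoothing is applied; the reconstruction is
exactly what the dequantized coefficients imply.

### Masked pixels

Detector gaps must never enter a wavelet transform (a sentinel leaking in
dominates every scale). Before encoding, invalid pixels are filled with
the lower median of valid neighbours in a 5x5 window, iterating so that
filled pixels become donors and arbitrarily wide gaps close from their
edges; after decoding, the mask (carried losslessly, bit-packed and
deflated) is reimposed, so no information is invented at invalid pixels.

## 4. Reduction operators and metadata

`BINn` replaces each n x n block by its sum — counts, not means, so
photon statistics remain Poisson — and `SUMm` adds m consecutive frames
pixel-wise, converting the phi slicing to an m-fold coarser one. Both are
linear sums over disjoint index sets, so they commute exactly and
conserve total valid counts; the tests assert both identities. Remainder
rows/columns/frames that do not fill a block are dropped, not padded
(padding would bias the sums), and the drop is recorded in the container
header. A superpixel containing any invalid source pixel is invalid: a
half-gap superpixel would otherwise masquerade as a low count.

Metadata propagates in lockstep: binning multiplies the pixel size by n,
floor-divides the pixel counts, divides the beam centre (kept in pixel
units precisely so this is a pure division), and maps gap rectangles to
superpixel coordinates with any overlap included; summing multiplies
oscillation width and count time by m. Summed counts stay signed 32-bit;
crossing 31 bits raises rather than wraps.

The 16-bit greyscale conversion for external wavelet codecs clips at
65535 with the clip count reported, and writes invalid pixels as 0 with
the mask carried separately. An 8-bit path is deliberately absent — it
discards too much dynamic range for diffraction backgrounds. The
JPEG-2000 stage itself is an adapter contract: a codec registered via
`options(mxsqueeze.wavelet_codec = ...)` receives the greyscale image and
a target ratio and must report its payload; with no codec registered the
stage errors with registration instructions, never a silent fallback.

## 5. Impact metrics

**Reflection profiles** average `n_rows` rows through the peak (default 6
on native frames, 3 on binned frames, matching how such comparisons are
conventionally displayed) and exclude invalid pixels per column; a fully
invalid column is `NA`, not 0.

**Peak survival** is classified from background-subtracted intensity `I`
in a circular window of radius `3 * sigma_px`, with background mean and
sigma from a surrounding annulus:

* **lost** — `I_after` fails the detectability test
  `I > 3 * sigma * sqrt(n_window)`, the conventional I/sigma(I) ~ 3
  weak-reflection floor. The sigma used is the *noisier* of the two
  annuli (reference vs test): a codec that flattens the local background
  to near-zero variance must not be credited with "detectability" against
  noise it erased, and this choice keeps the classification invariant
  under adding a common constant to both frames (which a Poisson-floor
  alternative would break).
* **boosted** — `I_after > 1.5 * I_before` (threshold `tau_boost`
  configurable): the accidental-inflation failure mode.
* **distorted** — windowed shape correlation below `rho_min = 0.9`.
* **preserved** — otherwise. Identical frames classify as preserved with
  zero deltas.

`tau_boost` and `rho_min` are configurable defaults, not measured
constants: the preserved/distorted/boosted/lost vocabulary is inherently
qualitative and the thresholds merely make it reproducible.

**Stack summaries** apply the classification to every non-occluded
ground-truth peak on its dominant frame (coordinates mapped through the
binning factor, frame indices through the summing factor), report
per-class fractions and per-frame background variance ratios, and flag
over-compression when the lost fraction exceeds a configurable bound
(default 0.2).

**Real-space R** compares density grids in two normalizations:
`sum(|ref - test|) / sum(|ref|)` (total density) and
`sum((ref - test)^2) / sum((ref - mean(ref))^2)` (variance of the
reference map as denominator). The variance-mode numerator is a stated
design choice — the squared form pairs naturally with a variance
denominator and is zero iff the grids agree — and a helper returns the
average of the two modes, the robust summary when the two normalizations
are plotted together. Density grids are inputs here; computing maps from
diffraction data is out of scope.

## 6. The synthetic scene generator

Each frame pixel is an independent Poisson draw with mean

```
b(r) + sum_p lambda[p, i] * G_p(row, col)
```

* `b(r) = background_base * exp(-r / background_decay_px) +
  background_floor`, radially symmetric about the beam centre: a
  two-parameter stand-in for the slowly varying scatter that lossy codecs
  feed on.
* `G_p` is an isotropic unit-mass spatial Gaussian truncated at 5 sigma.
* `lambda[p, i]` is the peak's total intensity times the Gaussian rocking
  curve mass inside slice `i` — this is what produces partial reflections
  split across consecutive frames, the feature that makes frame summing
  genuinely protective rather than merely smaller.

Sampling uses one seeded generator consumed frame-major, then in column
raster order within a frame, so identical configurations give
bit-identical stacks. Ground truth records every `lambda[p, i]`, the peak
table with occlusion flags (a peak centred in a gap), and expected
background means at four reference radii.

What the generator does **not** emulate: Ewald-sphere geometry, Lorentz
and polarization factors, diffuse scattering, ice rings, spatially
correlated detector noise, or per-module geometry. Passing tests
demonstrate codec and metric behaviour on data with the right *local*
statistics (Poisson background, compact Gaussian peaks, partiality,
gaps), not on the full physics of a diffraction experiment.

### Presets and study conditions

* `desk-small` — 512 x 512 px, 40 frames at 0.2°, background of a few
  tens of counts, 32 peaks (24 strong, 8 weak), two 10-px gap stripes.
  Sized to render in a couple of seconds; this is the default
  benchmarking corpus and the input for the acceptance script.
* `lysozyme-like` — 1800 frames at 0.2° (360° total), dense strong peaks,
  emulating a redundant low-energy sulfur-phasing collection.
* `rt-like` — 1200 frames at 0.2° (240° total), sparser weaker peaks,
  emulating a molecular-replacement collection.

The two full-series presets keep their true frame counts but scale the
detector plane down 16-fold per side from the 3269 x 3110 px of the
emulated detector (recorded in a `scale_factor` attribute); frame-count
metadata, not plane area, is what their tests exercise.

The weak-peak benchmark used by the test suite
(`tests/testthat/helper-scenes.R`) places six well-separated weak
reflections (sigma_px 1.0, sigma_phi 0.25° so each rocking curve spans
about 2.5 slices) on a flat background of 10 counts/px, with about 125
expected photons on the dominant frame — I/sigma(I) around 4 against the
3-sigma detectability floor. This SNR regime was chosen by mapping the
corridor in which a scale-4 H-transform pass preserves every peak while
scale 64 swallows most: the published behaviour of the Hcompress family
on weak MX reflections. Whether a particular peak survives scale 64
depends on how it happens to align with the dyadic coefficient blocks, so
the suite asserts zero losses at scales 0 and 4, a majority lost at 64,
monotone non-decreasing lost fraction and RMS error across scales
{0, 4, 8, 16, 32, 64}, and that BIN2+SUM2 pre-reduction never increases
the lost fraction at equal scale — the qualitative signatures, not a
per-peak prediction.

## 7. Numerical and container choices

* Coordinates are 0-based, row-major, half-open everywhere; one
  convention, no off-by-one ambiguity between formats.
* The gap sentinel defaults to the all-ones bit pattern of the stored
  4-byte dtype read as signed (`-1`); sentinels exist only at I/O
  boundaries, a boolean plane everywhere else. A sentinel below 2^16
  draws a warning because it collides with plausible counts.
* All binary container fields are little-endian; FITS output is
  big-endian as its standard requires. The native stack container (MXS)
  and compressed container (MXZ) are text-header + length-prefixed binary
  sections, self-describing, and byte-identical across platforms.
* The stack container is this package's own documented layout rather than
  an HDF5 subset: no HDF5 binding is declared as a dependency, and the
  layout (one text attribute block, one int32 cube) carries exactly what
  the pipeline needs. CBF support is a documented miniCBF-style subset
  whose binary section always goes through this package's byte-offset
  codec, so sizes and round trips are self-verified.
* Problem sizes in the tests (desk-scale stacks of 10^7 pixels,
  weak-peak scenes of 160 x 160 x 8) were chosen so the full suite and
  the acceptance script each run in well under a minute while still
  exercising every escape width, pyramid depth and classification branch.

## 8. Known limitations

* The H-transform bitstream is this package's dialect; it does not decode
  files produced by the astronomy program, by design (the variant id
  makes this explicit).
* The lost/boosted thresholds are reproducible conventions, not fitted to
  any ground-truth definition of "findable"; downstream spot finders may
  disagree near the boundary.
* Saturation is handled by mask propagation only; there is no special
  treatment of counts at the detector's saturation value during summing.
* The wavelet path requires an external codec; none is bundled.
* Scenes are single-panel with rectangular gap stripes; multi-module
  geometries with per-module orientation are out of scope.
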