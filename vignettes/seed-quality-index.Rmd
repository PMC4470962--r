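---
title: "Screening conifer seeds by a SWIR band-ratio angle: methods and design"
author: "seedsqi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening conifer seeds by a SWIR band-ratio angle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedsqi)
```

## The problem and the measurement

Anatomically unsound seeds of *Cryptomeria japonica* (sugi) and
*Chamaecyparis obtusa* (hinoki) — empty seeds and tannin-filled
"shibudane" — cannot be told from sound, potentially germinable seeds by
appearance, size or weight, and they dominate many stored seed lots. The
usable signal is spectroscopic: storage lipids in sound seeds absorb
strongly near 1,730 nm (first overtone of C–H stretching), so sound
seeds show an "m-shaped" SWIR reflectance spectrum with a narrow dip at
that band, while unsound seeds show a dip-free "n-shaped" spectrum.

A line-scanning SWIR camera images 18 seeds per plate (a 6 × 3 grid of
shallow wells) at roughly 320 × 200 px and 163 bands over
1,250–2,500 nm (7.7 nm spacing). Raw radiance is converted per pixel to
percent reflectance against a target of known reflectance
(`calibrateReflectance`): R = (raw − dark)/(reference − dark) × target%,
with the dark frame optional and zero by default — whether the
instrument's own calibration subtracts a dark frame is not observable
from outside, so both behaviours are exposed and the default is the
simpler one. Negative values clip to zero; non-positive reference pixels
are zeroed and counted rather than propagated as NaN, so downstream
masks stay total.

## The index

For percent reflectances $R_{1637}, R_{1734}, R_{1854}$ at the three
index bands, the seed quality index is the clockwise angle at the middle
vertex of the polyline through $(-1, R_{1637})$, $(0, R_{1734})$,
$(1, R_{1854})$:

$$\alpha = \frac{(R_{1637}-R_{1734})(R_{1854}-R_{1734})-1}
{\sqrt{(R_{1637}-R_{1734})^2+1}\,\sqrt{(R_{1854}-R_{1734})^2+1}},$$

with $\mathrm{SQI} = \tfrac{180}{\pi}\arccos\alpha$ when
$R_{1734} \le (R_{1637}+R_{1854})/2$ and $360$ minus that otherwise.

Three design points deserve emphasis:

* **The branch condition is the flank mean.** The typeset source of the
  two-branch rule is ambiguous; reading the condition as
  $R_{1734} \le (R_{1637}+R_{1854})/2$ is the only interpretation
  consistent with a clockwise-angle geometry and with continuity at
  180° (a collinear triplet gives $\alpha = -1$ on the branch
  boundary). The test suite checks the whole construction against an
  independent `atan2`-based planar-angle oracle, including continuity
  across the branch.
* **Unit x-steps, percent units.** The abscissae are unit steps, not the
  physical 97/120 nm band offsets, as the "+1" terms in $\alpha$
  imply. Consequently the index is *not* scale invariant: reflectance
  must be in percent. A dedicated test asserts the non-invariance to
  guard against fraction/percent unit bugs.
* **Clamping.** $\alpha$ is clamped to $[-1, 1]$ before `arccos` to
  absorb floating-point overshoot on near-collinear triplets.

`sqiAreal` averages the spectra over a seed's analysis mask first and
applies the index second; because the index is nonlinear this differs
from averaging pixelwise SQI values (a two-pixel example in the tests
shows ≈ 5.7° vs ≈ 91.4°). `sqiPixelMap` computes the index per pixel;
`pbr` is the strict fraction of map pixels below maxSQI. Strict
inequalities ("lower than", "greater than") are used for all selection
boundaries and are centralized in `selectSingle`, `selectDual` and
`pbr`.

Nominal index wavelengths are resolved to the nearest instrument bands
(`nearestBand`, default tolerance 5 nm — just over half the 7.7 nm band
spacing), so the package works unchanged on sensors with shifted band
centres.

## Segmentation

Seed areas are found by similarity to a pre-assigned reference
spectrum, by spectral angle (scale invariant) or Pearson
cross-correlation (affine invariant); both are provided because either
may suit a given illumination field, with configurable thresholds.
Components are extracted with 8-connectivity by default, holes filled
unconditionally (seed areas are closed), blobs under 10 px dropped, and
border-touching seeds excluded as unreliable. Margin erosion uses the
Euclidean distance transform rather than iterated structuring elements,
so a margin of *m* pixels means exactly "more than *m* px from
background" even across diagonal boundaries. All coordinates are
1-based (row, col), following R convention.

## Smoothing

The optional 3 × 3 denoising filter weights neighbours by
$2^{-d}$ with $d$ the Euclidean offset distance: centre 1, edges 0.5,
corners $2^{-\sqrt 2} \approx 0.3752$, kernel sum
$\approx 4.5009$. Weights renormalize over in-mask pixels only, so
constants are preserved and mask edges are not diluted by background.
The centre weight $2^0 = 1$ is the natural reading of the rule.
Smoothing is off by default everywhere: it exists for rendering, not
scoring.

## Selection and calibration

`selectionStats` implements the five rates (SR_init, RR, SR, YR, TER);
SR and YR are reported as missing (never 0) when their denominators
vanish. TER·N is always the integer misclassification count, and
RR·SR = YR·SR_init whenever both sides are defined — both are tested as
properties.

* **Single method.** Candidate thresholds are the midpoints between
  consecutive sorted distinct SQI_areal values plus sentinels below and
  above; this enumerates every selection a strict threshold rule can
  realize, so the sweep optimum is exact (verified against brute-force
  enumeration of all 2^N subsets on lots of ≤ 8 seeds). Among tied
  optima the smallest threshold is chosen — deterministic and the most
  stringent of the equally good options.
* **Dual method.** A grid search at 1-degree × 1% steps over
  [⌊min SQI_pixel⌋, ⌈max SQI_pixel⌉] × [0, 1], verified against a
  double-loop oracle. Tie-breaking among optimal cells takes the modal
  maxSQI among optima, then the modal minPBR *among optima at that
  maxSQI* (ties toward smaller values). The constraint to optimal cells
  is deliberate: unconstrained per-coordinate modes can combine into a
  pair that is not itself optimal, and the chosen pair must attain the
  reported minimum TER.
* **Cross-lot validation.** `crossValidate` calibrates on one lot and
  applies the chosen parameters unchanged to the other, reporting
  calibration and validation error with full statistics. Seeds whose
  regions become invalid (over-eroded or border-touching) are excluded
  from both roles and listed, since no principled imputation exists.

The TER curve is empirically bowl-shaped on well-behaved lots but that
is not guaranteed, so it is not asserted anywhere; likewise SR is only
monotone along the sweep when the classes are separable, and the test
that checks the SR/YR trends uses a separable lot.

## The synthetic generator

`generatePlate` emulates what the method assumes about real plates, at
the study's scale (18 seeds, 163 bands, 320 × 200 px):

* elliptical seeds (semi-axes 7–10 px, matching ~1 cm wells at
  ~106 ppi) on the 6 × 3 grid, over a dim background ramp around 5%
  reflectance that is spectrally distinct from seed tissue;
* a linear seed baseline ramp (55–70%) minus a Gaussian dip at 1,730 nm
  (σ = 35 nm): depth 15–25% for sound seeds, a 4–7% bump for
  shibudane, 0–1% for other unsound seeds. Sound-seed depth fades
  radially as $1-(r/R)^2$, placing the lowest pixelwise SQI at the seed
  centre;
* per-band additive Gaussian noise, and an optional multiplicative
  vignetting field applied to raw and reference cubes alike to exercise
  the pixelwise calibration (it cancels exactly);
* raw radiance defined as reflectance/target% × reference level, so
  calibration inverts the construction to machine precision.

Two presets encode the species contrast that motivates the dual method:
`sugiPlateConfig` keeps unsound seeds spatially flat (their areal SQI is
margin-invariant), while `hinokiPlateConfig` gives unsound seeds a small
(2–6%) central dip gradient as well, so they acquire nonzero PBR at
permissive thresholds and areal-SQI separation narrows. Class mixture
defaults to 9 sound / 6 shibudane / 3 other per plate.

What the generator does *not* emulate: realistic seed shapes, seed-coat
scattering, spatially correlated noise, specular artefacts, or the
absolute SQI ranges of either species (published only as figures).
Passing pipeline tests therefore demonstrate correctness of the
algorithms under the stated phenomenology, not field performance on
instrument data.

## Problem sizes and determinism

Pipeline tests run on 72 × 120 px plates with the full 163-band grid
(the spectral dimension matters for band resolution; the spatial extent
does not), and two camera-scale 320 × 200 plates are analysed end to
end in the acceptance tests — zero-noise, where segmentation must
recover truth masks exactly and both methods must reach TER = 0, and 1%
noise at a fixed generator seed, where at most one of 18 seeds may be
misclassified. Every stochastic test fixes its RNG seed; the generator
takes its seed from the configuration, making whole plates bit
reproducible.

## Known limitations

* ENVI support covers the common integer/float little- and big-endian
  types and BSQ/BIL/BIP interleaves, not the full header zoo (no BIP
  tiling, no external offsets).
* The spectral-angle map treats the whole cube; there is no
  illumination-robust continuum removal, which real plates with strong
  vignetting might need before thresholding (the gain-field option
  shows calibration alone already removes multiplicative fields).
* Touching seeds are not split (wells separate them physically); no
  shape or size features are used, which is deliberate — they carry no
  class signal in this system.
* Discriminating germinable from dormant-but-sound seeds is out of
  scope: the index measures anatomical soundness, a necessary but not
  sufficient condition for germination.
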