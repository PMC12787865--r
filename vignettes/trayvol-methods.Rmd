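---
title: "Depth-based food volume estimation: model, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-based food volume estimation: model, assumptions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trayvol)
```

## The estimation model

`trayvol` quantifies served portions from a single overhead view. Its input
is not metric range data but the output of a monocular relative-depth model:
a dense raster of unitless values, normalized to roughly $[0, 1]$, whose
ordering reflects elevation but whose scale and zero point are arbitrary.
Two geometric facts drive the design.

First, monocular depth models systematically hallucinate a planar tilt
across flat scenes — a perspective cue misread as geometry. Summing raw
depth over a food mask therefore biases volumes, increasingly so for items
far from the image center. The pipeline removes the tilt by exploiting a
physical prior: the outer rim of a plate is flat. The rim band (the annulus
of width $b$ just inside the plate mask, food pixels excluded) is sampled,
and a base plane

$$z = a x + b y + c$$

is fitted to the samples by least squares. Subtracting the plane re-centers
every pixel's depth to height above the plate surface:

$$z_{\mathrm{corr}}(x, y) = z_{\mathrm{depth}}(x, y) - (a x + b y + c).$$

Second, with depth measured relative to the plate, each pixel is a vertical
prism of base area $s^2$ and height $z_{\mathrm{corr}}$. The volume of item
$i$ with mask $M_i$ is the positive-part sum

$$V_i = \sum_{(x,y) \in M_i,\ z_{\mathrm{corr}} > 0} z_{\mathrm{corr}}(x, y)\, s^2 .$$

Pixels at or below the base plane contribute nothing: they are plate
surface, segmentation spill-over, or noise, not food. Volumes are in
arbitrary units (a.u.) — valid for comparisons across items and frames —
until $s^2$ or a downstream density model supplies a physical scale.

Weights follow from a per-food-class density model fitted to calibration
pairs $(V_j, w_j)$. The default form is proportional through the origin,
$w = k V$, the physical premise that weight is density times volume; its
least-squares solution is the closed form $k = \sum w_j V_j / \sum V_j^2$.
An affine variant ($w = kV + c$, ordinary least squares, predictions
floored at 0 g) is available for foods where segmentation systematically
misses or adds a fixed offset.

Robustness of the whole chain is summarized the way repeated-measures
stability is normally reported: each pass of a plate under the camera
yields a block of frame-level volumes, reduced to mean, sample standard
deviation ($n-1$ denominator — per-pass frame counts are small), and the
coefficient of variation $\mathrm{CV} = 100\,\mathrm{SD}/\mathrm{mean}$.
A pooled CV over the concatenated frames (never over block means) captures
frame-to-frame fluctuation across the experiment.

### Assumptions

* The plate rim is physically flat and visible; at least part of it is not
  covered by food. A frame whose rim band is empty after food exclusion is
  a typed failure (`"rim unavailable"`), never a silent zero.
* The depth map's *polarity* — whether larger values mean nearer the
  overhead camera — is declared, not guessed. Depth models differ on this
  convention, and the correction and integration steps require food tops to
  have larger values than the plate; every depth map carries a polarity tag and
  `normalize_polarity()` flips values as `max − v` when needed. The
  pipeline default assumes `higher_is_elevated`, the common convention for
  relative-depth networks viewed top-down, and exposes it in
  `pipeline_config()`.
* Masks are aligned to the depth raster at native crop resolution. When a
  fixed model input size is configured (conventionally 512 × 512), depth is
  inferred at model size and resampled *back* to the crop, so masks never
  move.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `band_width` | 5 | px | Width of the rim annulus (mask minus its erosion). Wider bands average more samples but creep toward the curved plate interior. |
| `clip` | `TRUE` | — | Zero out negative corrected depth. Integration only sums strictly positive values either way; clipping additionally sanitizes the persisted corrected map. |
| `pixel_area` | 1 | length² | $s^2$ in the prism sum. Scales all volumes linearly; metric calibration is deliberately out of scope. |
| `polarity` | `higher_is_elevated` | — | Depth convention delivered by the backend. |
| `model_size` | `NULL` (native) | px | Fixed depth-model input size; `NULL` skips the resample chain. |
| `max_points` (rim) | 5000 | points | Deterministic uniform-stride cap on rim samples; bounds the fit cost with no RNG. |

## What the synthetic scenes emulate — and what they do not

Real validation imagery for this problem (cafeteria trays, trained
detector/segmenter/depth networks) cannot ship with a package, and trained
weights are not this package's contribution. The synthetic-scene module
replaces them with scenes where every quantity the geometry is supposed to
recover is known exactly:

* the perspective tilt artifact, as a true plane $(a, b, c)$ added to the
  whole raster — magnitudes up to $|a|, |b| \le 0.1$ per pixel, our choice,
  since no quantitative artifact model is available;
* a flat plate whose rim is the fit support, with the plate surface at the
  plane level;
* food items as solids with closed-form volumes — spherical caps
  ($\pi h^2 (R - h/3)$), cones ($\tfrac13 \pi r^2 h$), boxes ($w l h$) —
  rasterized as elevation fields on the pixel grid, with depth units tied
  to pixel length units so analytic volumes come out in pixel³ = a.u.;
* repeated passes, as rotation sequences: each item's center orbits the
  plate center by the pass angle while the item keeps its orientation.
  Ground-truth volumes are invariant across a sequence; only rasterization
  changes. (Orbiting *with* an equal spin would be a rigid rotation of the
  whole plane and could never produce the off-plate collision the sequence
  generator is required to detect; orbiting without spin keeps that error
  reachable and still yields distinct masks for rotationally symmetric
  items.)
* i.i.d. Gaussian depth noise, applied after shape composition, seeded
  (default seed 0), standard deviation in depth units where the
  relative-depth range is order 1 — the standard noise level studied is
  0.005, i.e. 0.5 % of the range.

The mock perception backend serves manifest detections, ground-truth masks,
and the scene raster bit-deterministically, so any pipeline result equals
feeding the rasters straight to the geometry functions ("backend-bypass
equivalence", asserted to 1e−9 in the tests).

What passing these tests does **not** show: robustness to the failure modes
of real perception — depth models' texture dependence on smooth foods,
segmentation boundary errors on irregular items, occlusion, lighting. The
synthetic scenes validate the *geometry and statistics* given correct
perception inputs; they cannot validate the perception itself.

## Numerical choices

* **Plane fit.** SVD of the $[x\; y\; 1]$ design matrix rather than normal
  equations; a singular-value ratio below $10^{-10}$ raises
  `"degenerate plane fit"` (collinear rim points, < 3 points). Noiseless
  planar input is recovered to 1e−9 absolute.
* **Positive-part threshold.** Exactly 0, no epsilon: the stated retention
  rule is "positive values", and an epsilon would bias small items.
* **Accumulation.** All volume and statistics accumulation in 64-bit
  doubles regardless of raster storage precision; the prism sum adds many
  small terms.
* **Rim band.** Morphological erosion (box structuring element of radius
  `band_width`) with out-of-image treated as background; band points
  ordered row-major; subsampling by uniform stride, never RNG.
* **Box rasterization.** Half-open footprint
  $[-w/2, w/2) \times [-l/2, l/2)$ in the box frame: a box whose edges fall
  exactly on pixel centers keeps one boundary row/column, matching its
  continuous area (the symmetric strict inequality loses a full row and
  column in that alignment).
* **Depth resampling.** Align-corners bilinear interpolation
  (`src = dst · (n_{src}-1)/(n_{dst}-1)`): every sample position lies
  inside the source grid and bilinear interpolation is exact on affine
  fields, so planar rasters pass the down/up chain unchanged (≤ 1e−6) and
  base-plane correction commutes with resampling on plane-only scenes.
* **Raster storage.** Depth persists as 32-bit float TIFF, min-max
  normalized on write with scale/offset recorded in a JSON sidecar (float
  TIFF semantics are only well-defined on $[0,1]$); masks as 8-bit PNG.
* **Degenerate inputs.** Empty item masks yield zero-volume estimates with
  a warning (one bad item must not abort a multi-item frame); missing tray
  or rim are typed per-frame failures excluded from statistics and counted
  in the report; single-frame blocks report `NA` SD/CV rather than failing
  the sequence.
* **Tray selection.** Highest confidence, ties broken by larger box area.
* **Prompt matching (mock segmenter).** Intersection-over-union between the
  prompt and each item box, so a prompt matches the item whose box it best
  fits rather than any larger box (the plate) that merely contains it.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle: plane
fits against generating coefficients, volume integration against both
closed-form solid volumes and a brute-force per-pixel loop (and, for the
spherical cap, numerical integration on a 4× finer grid), statistics
against a two-pass implementation, calibration against the generating
density factor.

Standard problem sizes, chosen to keep the full suite comfortably fast
while leaving rasterization error well below the tolerances being tested:
512 × 512 px as the reference scene resolution (volume recovery ≤ 2 %
tolerance; observed cap error ≈ 0.001 %), 128/256/512 for the resolution
convergence study, 256 × 256 for the 20-replicate noise studies, 20
calibration pairs per fit. The calibration generator models a graded
portion ladder — evenly spaced volumes from a base portion to 3× it, with
5 % multiplicative log-normal weight noise — the way volume-to-weight
conversion tables are built from controlled portion series. Note that with
20 pairs and 5 % noise the standard error of $\hat k$ is ≈ 1.1 %, so a 2 %
recovery band is an ≈ 1.8 σ statement: it holds for the default seed used
in the tests and for most, but not all, seeds.

## Known limitations

* Volumes are relative; nothing here converts a.u. to cm³. Weight
  estimates inherit whatever bias the calibration pairs carry.
* The rim prior fails for rimless or deep bowls, stacked plates, or rims
  fully covered by food; such frames fail loudly by design.
* Occlusion, inter-item contact, and overlapping foods are excluded from
  the synthetic ground truth (overlap is a scene-construction error), so
  the pipeline's behavior on merged masks is unspecified beyond summing
  what the masks contain.
* The positive-part rule clips genuine concavities below the rim plane
  (e.g. food in a recessed plate well) to zero.
* Real-model adapters (detector, prompt segmenter, depth network) are out
  of scope; the S3 backend generics are the extension point, and results
  with real models will add perception error on top of everything
  quantified here.
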