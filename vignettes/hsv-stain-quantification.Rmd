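---
title: "Quantifying histological stains by HSV thresholding"
author: "hsvstain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histological stains by HSV thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsvstain)
```

## The problem

Digital histology quantifies a stain by counting the pixels whose color says
"positive" and reporting them as a percent of a region of interest (ROI).
The obstacle is that the *same* tissue does not present the same color from
section to section: a slightly thicker cut binds more stain and transmits
less light, folds locally double or triple the optical path, focus drifts
across a tilted slide, and images get rescaled. All of these move pixel
colors substantially in RGB coordinates, so a fixed RGB threshold box tuned
on one section misclassifies its neighbors.

The observation this package is built on is that those artifacts move colors
along *specific* axes of the hue–saturation–value (HSV) space: thickness and
folds raise saturation and lower value but leave hue — the stain's dominant
wavelength — essentially untouched. A threshold that is tight in hue and
deliberately wide in S and V therefore keeps selecting the same tissue class
across sections of varying thickness, through folds, and under blur, while
the equivalent RGB box does not.

## The color model

Images enter as 8-bit RGB (`h x w x 3` arrays, values 0–255). `rgb_to_hsv()`
maps them to the hexcone parameterization with hue in degrees on
$[0, 360]$ and S, V on the 8-bit scale $[0, 255]$:

$$V = \max(R, G, B), \qquad
  S = 255\,\frac{\max - \min}{\max} \;(\text{0 when } \max = 0),$$

$$H = \begin{cases}
  60\,(G - B)/\Delta & \text{if } R \text{ is the maximum}\\
  60\,\bigl(2 + (B - R)/\Delta\bigr) & \text{if } G \text{ is the maximum}\\
  60\,\bigl(4 + (R - G)/\Delta\bigr) & \text{if } B \text{ is the maximum}
\end{cases}$$

with $\Delta = \max - \min$ and $360$ added when the red branch is negative.
Three edge cases are fixed by convention so the map is total and
bit-reproducible:

* **achromatic pixels** ($\max = \min$): the hue ratio is $0/0$; we define
  $H = 0$ and rely on $S = 0$ to mark the pixel as gray;
* **black** ($\max = 0$): $S = 0$, the only self-consistent completion;
* **ties for the maximum channel**: branch priority is fixed as R, then G,
  then B. At a tie every applicable branch yields the same hue, so the rule
  only pins down reproducibility, not the value.

The inverse `hsv_to_rgb()` recovers any chromatic 8-bit triple exactly after
rounding; the test suite verifies the round trip on dense grids and checks
the forward map against an independently written scalar transcription and
against `grDevices::rgb2hsv()` (up to the axis scaling).

H and S are kept in floating point internally. Thresholding benefits from
unrounded values; printed tables round for display only.

## Threshold cuboids

A *threshold cuboid* (`threshold_cuboid()`) is an axis-aligned box in HSV or
RGB; a pixel is positive only when **all three** of its components lie in
their closed `[min, max]` intervals. Closed intervals are the least
surprising reading of "between"; with integer 8-bit data the difference is a
boundary pixel at most. Up to three cuboids form a `threshold_set()`,
letting one pass extract, e.g., muscle, collagen and necrotic tissue.

Hue is circular, and red stains sit exactly on the wrap. Rather than forcing
two boxes, a hue interval may extend past 360 (up to 720): `h = c(300, 385)`
selects $[300, 360] \cup [0, 25]$, and membership tests both $H$ and
$H + 360$. Density-map rendering extends the hue axis the same way so such a
cuboid is drawn as one rectangle crossing the 360 line.

Nothing in the definition prevents cuboids from overlapping, so
`apply_threshold_set()` reports counts both ways:

* **independent** — each cuboid tested on its own; a pixel in two boxes
  counts for both (three genuinely independent threshold sets);
* **exclusive** (default) — first-match priority in list order, so class
  counts plus the unassigned count partition the ROI exactly. Overlays use
  the exclusive assignment, giving each pixel a unique display color.

Percent positive area is $100 \cdot \text{count} / \text{ROI pixels}$. The
denominator is always the ROI size — the whole image when no mask is given,
minus fully transparent pixels when the image has an alpha channel (a
transparent pixel carries no stain information). Callers wanting
tissue-relative percentages pass a tissue mask as the ROI.

## Density maps

`project_density()` bins the ROI pixels over one coordinate plane of the
color space (H–S, H–V, S–V, or the RGB pairs); the stored histogram always
covers the full axis ranges so its mass equals the ROI pixel count exactly.
The default 128 bins per axis resolve the class clusters of a stained
section at desk scale. `render_density()` log-scales counts for display only
— heavy-tailed pixel clouds are unreadable on a linear ramp — and overlays
the threshold rectangles. The hue-axis extension for wrapped cuboids is a
*rendering* device (low-hue columns are duplicated past 360); the stored
grid keeps hue on $[0, 360]$ so mass conservation is never violated.

## The synthetic test bed

No real sections ship with the package; robustness claims are exercised on
a ground-truthed generator (`synthetic_scene()` / `generate_scene()`).

The generator carves class regions out of a smooth random scalar field by
rank: pixels are sorted by field value and the first
`round(fraction * N)` of them assigned to each class, so each class's pixel
count — the denominator of every downstream check — is exact by
construction, while the regions stay spatially coherent (an infarct-like
nested geometry by default: muscle ring, collagen interior, optional
necrotic core, on a near-white background).

Default study conditions, chosen once to emulate a trichrome-stained
infarcted section and not revisited:

| parameter | default | why |
|---|---|---|
| muscle color | RGB (205, 70, 48), hue ~8.4° | scarlet red of the muscle counterstain |
| collagen color | RGB (55, 75, 190), hue ~231° | aniline blue |
| necrotic color | RGB (70, 40, 75), V = 75 | dark purple, low brightness |
| background | RGB (247, 245, 235) | near-white slide, faint warm cast |
| fractions | 0.45 / 0.20 (/ 0.05) | a large infarction; remainder background |
| S/V jitter σ | 10 | stain-density gradient within a class |
| hue jitter σ | 0 (option) | thickness-type artifacts do not move hue; enable to stress hue bands |

The muscle hue sits at ~8° rather than straddling 0/360 deliberately:
achromatic background pixels take $H = 0$ by convention, and a
red band wrapped across 0 would swallow them through the wrap rule. Wrap
semantics are exercised separately with an explicit 300–385 band.

What the generator does **not** emulate: optics-accurate point-spread
functions, chromatic aberration, stain co-localization, texture within a
class, and compression artifacts. Passing robustness tests here shows the
*mechanism* (hue invariance under S/V excursions) works as claimed, not that
any particular real stain will land inside a given hue band.

### Perturbations

* **Thickness** (`apply_thickness()`): per pixel, $S' = \min(255, tS)$,
  $V' = \min(255, V/t)$, hue untouched. The linear single-factor model is
  the simplest encoding of "more stain, less light"; a Beer–Lambert-type
  exponential would be the physical alternative, and the transform is
  isolated so it can be swapped. The point under test — hue invariance — is
  shared by any model that moves only S and V.
* **Fold** (`apply_fold()`): a region behaves like tissue `layers` (2 or 3)
  times thicker; outside pixels are untouched. Regions are logical masks or
  polygons (even-odd rasterization).
* **Defocus** (`apply_defocus()`): Gaussian blur whose sigma ramps linearly
  from 0 at the top edge to `max_radius` at the bottom, emulating a tilted
  slide; rows are linear blends of integer-sigma blurred copies
  (kernels normalized, so intensity is conserved up to boundary effects).
* **Downsampling** (`downsample_image()`): area averaging by a linear
  factor, `ceiling` geometry for non-divisible edges (3000 px at factor 16
  gives 188).

## Fixed-threshold robustness experiments

`run_robustness_experiment()` replays the protocol of tuning once and
holding parameters fixed: thresholds for both methods are fit on the
unperturbed reference scene from its ground-truth labels, then applied
unchanged to every perturbed condition; percent areas are normalized to the
reference condition.

The fitting rule (`fit_class_thresholds()`) is a reproducible stand-in for a
human with sliders: per class, the 1st–99th percentile range of the class
pixels, widened by a 5-unit margin (degrees in hue, intensity units in RGB).
The margin reflects that nobody sets sliders at the exact percentile —
a bare percentile band on a nearly constant hue collapses to about a degree
and would be brittle against boundary-pixel color mixing for *both*
methods. The same probabilities and margin apply to both spaces, so the rule
favors neither method structurally; the difference under test is only
*which axes* are constrained. In HSV the hue band is fit and S/V stay at
full width $[0, 255]$ (the box spans any thickness excursion by
construction); in RGB all three channels get percentile boxes, the natural
analogue for that space.

The "magnification" experiment is modeled as sampling-density change over a
fixed field of view — area-average resampling of the reference render —
i.e. the inverse of the downsampling experiment; real objective lenses
change optics as well, which is out of scope here.

```{r experiment, eval = FALSE}
rep <- run_robustness_experiment("thickness", seeds = 1:4, size = 256)
rep$summary
```

Problem sizes used by the shipped checks, chosen as the package's own
working scale: thickness and fold experiments run on 256-pixel-square
scenes (the effect sizes are large and resolution-independent); the
1/16-downsampling check runs on a 1504-pixel-square scene so that the
downsampled image (94 px square) still resolves the class regions — at tiny
scene sizes the result measures boundary-pixel mixing, not the method. The
range scan of the conversion covers the full 16.7M-triple RGB cube in the
acceptance script and a dense 64-level grid in the unit tests.

## Numerical and design choices

* All counting is exact integer arithmetic on logical masks; the only
  floating-point quantities are HSV values and percents.
* Conversion rounding: images written to disk are 8-bit; a
  thickness/fold transform therefore costs at most one intensity level of
  rounding per channel, which the identity checks (`t = 1`) account for.
* Degenerate inputs: empty ROIs, dimension mismatches and space mismatches
  are errors, not silent recoveries; an all-negative threshold set is a
  valid result (0%, background-only overlay).
* Scene generation saves and restores the global RNG state, so library
  calls do not perturb user simulations.
* GIF and BMP support is provided by small built-in codecs (uncompressed
  24/32-bit BMP; LZW GIF, first frame of animations) since the lossless
  scientific path is PNG/TIFF; JPEG input warns that chroma subsampling
  perturbs hue.

## Limitations

* Thresholds are user-supplied (or percentile-fit from labels); there is no
  automatic threshold learning.
* The thickness model is linear and unvalidated against physical optics; it
  is a mechanism probe, not a calibration.
* Percent-area comparisons on real stained tissue require real images;
  the synthetic suite demonstrates the selection mechanism only.
* Whole-slide pyramidal formats and CMYK inputs are out of scope.
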