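# hsvstain

Quantification of histological stains by thresholding in the
hue–saturation–value (HSV) color space.

## Why

Histology quantifies a stain by counting positive pixels and reporting them
as a percent of a region of interest (ROI). Section thickness variation,
folds, defocus and rescaling all shift pixel colors — but they shift them
along *saturation* and *value*, while *hue* (the stain's dominant
wavelength) stays put. A threshold box that is tight in hue and wide in S/V
therefore keeps measuring the same tissue class across imperfect sections,
where an RGB threshold box tuned on one section fails on the next. This
package implements that analysis for researchers and pathologists doing
quantitative image analysis of stained sections.

## What it computes

Pixels are mapped from 8-bit RGB to `H ∈ [0, 360]`, `S, V ∈ [0, 255]`:

    V = max(R, G, B)
    S = 255 · (max − min) / max          (0 when max = 0)
    H = 60·(G−B)/Δ          if R is max     (+360 if negative)
        60·(2 + (B−R)/Δ)    if G is max
        60·(4 + (R−G)/Δ)    if B is max

A *threshold cuboid* is a closed box in HSV (or RGB, the comparison
baseline); a pixel is positive only if all three components fall inside.
Hue intervals may extend past 360 (e.g. `[300, 385]`) to straddle the red
wrap. Up to three cuboids are applied at once; results are pixel counts,
percent of ROI (`100 · count / ROI pixels`), recolored overlays, and 2-D
color-plane density maps with the threshold rectangles drawn. A
ground-truthed synthetic stained-section generator with thickness, fold,
defocus and downsampling perturbations drives the robustness experiments.

## Worked example

```r
library(hsvstain)

rgb_to_hsv(c(128, 0, 128))   # dark violet
#>   H   S   V
#> 300 255 128

# synthetic trichrome-like section with exact ground truth
gen <- generate_scene(synthetic_scene(512, 512,
  classes = trichrome_classes(necrotic = TRUE), seed = 42))

# fit hue-banded, full-S/V thresholds on the reference labels
ts  <- fit_class_thresholds(gen$image, gen$labels, "HSV",
                            names(gen$class_counts))
res <- extract_three_colors(convert_image(gen$image, "HSV"), ts)
res
#> Color extraction (HSV space, exclusive counts)
#> ROI pixels: 262144
#>     label pixel_count percent_area
#>    muscle      117965      45.0001
#>  collagen       52429      20.0001
#>  necrotic       13107       4.9999
#> unassigned: 78643
```

The scene was built with 45% muscle, 20% collagen and 5% necrotic area; the
HSV thresholds recover those percents to within a few thousandths of a
percent (the residual is boundary pixels whose jittered colors mix).
Holding the same thresholds fixed while the section "thickness" changes:

```r
run_robustness_experiment("thickness", seeds = 1, size = 256)
#> Robustness experiment: thickness (256x256 scene, 1 seed)
#> Max relative deviation from reference condition (%):
#>  method max_rel_dev
#>     HSV     0.00000
#>     RGB    99.96584
```

The HSV measurement is unchanged across thickness factors 0.8–1.2 while the
RGB baseline, tuned on the same reference image, loses essentially all of a
class — the sample-to-sample variation the method eliminates.

A command-line front end wraps the same functions
(`inst/cli/hsvstain.R`; subcommands `analyze`, `compare`, `density`,
`synth`, `reproduce`), writing overlays, masks, CSV results and JSON
summaries.

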