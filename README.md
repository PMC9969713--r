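# pscplant

Fast 3-D reconstruction and trait evaluation of potted plants from a pair
of opposed RGB-D depth cameras.

## The problem

Plant architectural traits — height, width, length and bounding-box
volume — are standard phenotyping quantities, usually measured on a 3-D
point-cloud model of the plant. Multi-view modeling normally relies on
correspondence-based registration (ICP), which is slow and fails outright
when views do not overlap. For a *fixed, calibrated rig* of two
mirror-symmetric depth cameras facing each other across the pot (each
700 mm from the pot centre, a 1400 mm baseline), no correspondence search
is needed: the second camera's cloud maps into the first camera's frame by
a closed-form rigid motion — the point-cloud spatial-coordinate (PSC)
method. `pscplant` is aimed at plant-phenotyping researchers who want that
pipeline end to end, plus the tooling to validate it without hardware.

## The method

For a depth pixel at (row *v*, column *u*) with depth *d* mm, back-projection
uses the inverse pinhole model (camera frame: +Z forward, +Y up)

    x = (u − cx)·d/fx,   y = −(v − cy)·d/fy,   z = d

and color is attached by projecting into the color camera after the
calibrated depth-to-color rotation/translation and taking the nearest
pixel. Two filters clean each view: a PassThrough crop to the region of
interest (x ∈ (−200, 200), y ∈ (0, 400), z ∈ (500, 900) mm by default),
and statistical outlier removal keeping points whose mean distance *d̄* to
their *m* nearest neighbours satisfies μ − kσ ≤ d̄ ≤ μ + kσ (defaults
m = 35, k = 1.0, selected by a two-pass coordinate descent that the
package also implements). The second view is then mapped into the first
camera's frame by

    (x, y, z) → (−x, y, −z) + (0, 0, B),    B = 1400 mm,

the clouds are spliced directly, and traits are read off the axis-aligned
bounding box: height = Y extent, width = X extent, length = Z extent (mm),
volume = H·W·L/1000 (cm³). Model accuracy against manual measurements is
scored per trait as AP = (1 − |M − C|/M)·100 and summarised by the
synthetic accuracy Acc, the equal-weight mean of the four APs.

The package also provides a virtual dual-camera rig (procedural plant
scenes, z-buffer depth rendering, a Kinect-like radial noise model) with
exact ground truth, and a point-to-point ICP baseline (kd-tree
correspondences + Kabsch/SVD updates) for speed/accuracy comparisons on
synthetic turntable captures. See the vignette
(`vignettes/reconstruction-methods.Rmd`) for the full model description
and design rationale.

## Worked example

Simulate a noisy dual capture of a procedural plant and reconstruct it:

```r
library(pscplant)

scene <- generatePlant(PlantSpec(seed = 5))
scene@traits
#> TraitSet  H 358.9 mm  W 271.4 mm  L 285.1 mm  V 27770.61 cm^3

cap <- simulateDualCapture(scene, noise = NoiseSpec(seed = 5))
res <- runPipeline(PipelineConfig(), cap$view1$depth, cap$view1$color,
                   cap$view2$depth, cap$view2$color)
#> view 1 passthrough: 45380 -> 11737 points
#> view 1 statistical: 11737 -> 10832 points (mu 8.96, sigma 5.05 mm)
#> view 2 passthrough: 47832 -> 14595 points
#> view 2 statistical: 14595 -> 13989 points (mu 7.93, sigma 4.70 mm)
#> fused model: 24821 points; traits H 358.7 W 273.9 L 296.0 mm, V 29090.51 cm^3

round(syntheticAccuracy(scene@traits, res$traits), 2)
#> [1] 97.62
```

The passthrough counts show the background (pot, backdrop, outliers
outside the working box) being cropped; the statistical filter then
removes sparse noise. The reconstructed height is within 0.2 mm of ground
truth; the length is 11 mm long because surviving near-plant noise
stretches the Z extent — volume compounds the three axis errors, giving a
synthetic accuracy of 97.6%.

Evaluating the bundled measured-vs-calculated trait records (20 plants ×
3 growth stages) reproduces the published accuracy summary:

```r
rep <- evaluateBatch(plantTraitRecords("all"))
rep
#> EvaluationReport  60 records, 3 stages
#>      stage ap_height ap_width ap_length ap_volume   acc
#>     sprout     95.88    95.16     89.25     89.17 92.37
#>   seedling     98.05    94.65     91.23     89.29 93.30
#>  flowering     98.19    96.18     91.58     92.38 94.58
#> overall:  ap_height 97.37  ap_width 95.33  ap_length 90.69  ap_volume 90.28  acc 93.42
round(rep@r2, 4)
#> height  width length volume
#> 0.9956 0.9654 0.9126 0.9817
```

Each `ap_*` column is the stage-mean accuracy percentage of one trait;
`acc` is the synthetic accuracy. Height is recovered best (R² = 0.9956
against manual measurement); length worst, because depth-edge noise erodes
the extent along the viewing axis.

A thin CLI over the same functions is installed at
`inst/scripts/pscplant` with subcommands `convert`, `filter`, `fuse`,
`traits`, `evaluate`, `simulate` and `compare-icp`.

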