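# smpdiou

Bounding-box regression losses for small-object detection in pathology
images, with the analysis tooling to compare them.

Detectors that localise lymphocytes in labial-gland biopsy slides (the
tissue evidence behind a Sjögren's syndrome diagnosis) are trained with an
IoU-based bounding-box loss.  This package implements the whole family —
IoU, GIoU, DIoU, CIoU, EIoU, SIoU, MPDIoU — plus **S-MPDIoU**, an
angle-adaptive corner-distance loss:

```
S-MPDIoU = IoU − scale · (d₁²/C² + d₂²/C²),   scale = log₂(downsample)
```

where `d₁`, `d₂` are the distances between the two boxes' top-left and
bottom-right corners, and the baseline `C` is chosen from the angle
`α = arctan(C_h/C_w)` between the box centers: `C` spans the feature map's
width for flat angles (`w₁ = W, h₁ = W·tanα` when `α < π/4`), its height
for steep ones (`w₁ = H/tanα, h₁ = H` otherwise), and the full diagonal
`√(W²+H²)` at `α = π/4`.  Shrinking the baseline for near-axis-aligned
pairs and amplifying the penalty by the constant `scale` keeps the
gradient alive exactly where a fixed-diagonal penalty (MPDIoU) stalls:
boxes that are close but not yet overlapping.

Every metric is exposed as a similarity and as a loss `1 − m` with
closed-form gradients (verified against finite differences), consumed by
a vectorised gradient-descent simulator that measures epochs-to-
convergence on fixed and randomised box populations.  The package also
ships the **MDA** (Multi-Dimensional Attention) operator — channel
attention via spatial pooling and an adaptive bias-free 1-D convolution,
followed by width- and height-direction attention, learning only `k`
scalars — and a desk-scale **slide triage** pipeline (background
filtering, 640×640 tiling, pluggable per-patch cell counting, threshold
flagging, red overlay), exercised end to end on synthetic H&E-like
slides with a known cell ledger.

## Worked example

```r
library(smpdiou)

g <- FeatureMapGeometry(20)       # 20x20 map of a 640 input
g
#> FeatureMapGeometry: 20 x 20 cells (input 640 px, downsample 32, scale 5)

gt   <- BBox(1, 1, 0.5, 0.5)      # ground truth
pred <- BBox(7, 1, 1, 2)          # horizontally displaced prediction
mpdiou(gt, pred, g)               # fixed-diagonal penalty
#> [1] -0.0915625
smpdiou(gt, pred, g)              # angle-adaptive, scale-amplified
#> [1] -0.915625
```

The pair is disjoint, so plain IoU is 0 and flat; the S-MPDIoU penalty is
10× MPDIoU's here (baseline 20 instead of the diagonal √800, squared →
2×, times scale 5).  That translates directly into convergence speed:

```r
e1 <- experiment1(c("mpdiou", "smpdiou"))   # three fixed configurations
e1
#>      loss       case convergedEpoch    finalGap
#> 1  mpdiou horizontal           5733 0.009513013
#> 2  mpdiou   diagonal           5901 0.007807050
#> 3  mpdiou   vertical           4802 0.004797563
#> 4 smpdiou horizontal            598 0.009627382
#> 5 smpdiou   diagonal           1385 0.009492474
#> 6 smpdiou   vertical            596 0.004719333
speedupRatios(e1)[4:6, ]
#>      loss       case  speedup
#> 2 smpdiou horizontal 9.586957
#> 4 smpdiou   diagonal 4.260650
#> 6 smpdiou   vertical 8.057047
```

Gradient descent (rate 0.02, threshold 0.01 on the L1 parameter gap)
converges 8–10× faster under S-MPDIoU in the axis-aligned cases — where
the adaptive baseline shrinks — and ~4× faster diagonally, where only the
scale constant separates the two losses.  `experiment2()` runs the same
comparison over a randomised population of 85,750 cases (subsampled for
desk-scale runs); on the 40×40 map S-MPDIoU ends with the lowest total
gap of all eight losses.

A thin command-line front end over these functions is installed at
`inst/scripts/smpdiou-cli.R` (`loss-eval`, `sim1`, `sim2`,
`mda-selftest`, `fixtures-make`, `triage-run`).

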