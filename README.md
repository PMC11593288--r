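# hepatomorph

Morphometric analysis of the sagittal left-liver-lobe contour for liver
fibrosis staging.

In chronic liver disease the left lobe's cross-sectional shape changes:
the dorsal (rear) capsule becomes irregular and the lobe thins, so the
minor axis of the best-fitting ellipse of its sagittal section falls with
fibrosis stage (F0–F4, Brunt classification). `hepatomorph` implements the
image-analysis side of that observation for researchers working with
B-mode ultrasound segmentations: given a binary mask of the left-lobe
section it computes the classical particle-analysis descriptor set

- polygon `Area` (shoelace) and `Perimeter` (traced pixel-center polygon,
  diagonal steps √2), `Circularity = min(1, 4πA/P²)`,
- `Solidity = A / A_hull`,
- `Feret` / `MinFeret` caliper diameters by rotating calipers over the
  convex hull, with `FeretAngle` in the y-up frame,
- the equal-area moment ellipse (`Major`, `Minor`, `Angle`),
  `AspectRatio = Major/Minor`, `Roundness = 4A/(πMajor²)`,
- bounding-box `Width`/`Height`,

plus a rear-surface roughness statistic (RMS residual of the rear contour
against its moving-average smoothing, with a calibrated smooth/rough
threshold), segmentation overlap metrics (`IoU = TP/(TP+FP+FN)`,
`F = TP/(TP+(FP+FN)/2)`, Dice loss `1−F`), and the staging statistics:
Jonckheere–Terpstra trend tests of each feature across ordered stages and
ROC/AUROC with Youden operating points for the ≥F3 and F4 endpoints.

Because clinical ultrasound images are not publicly deposited, the package
ships a synthetic cohort generator: superellipse-based left-lobe phantoms
with known stage-dependent minor-axis thinning, stage-dependent rough-rear
prevalence, and Rayleigh-like speckle rendering, so the entire pipeline is
testable end to end against ground truth.

## Worked example

```r
library(hepatomorph)

res <- runPipeline(runConfig(seed = 1), outputDir = "run1", verbose = FALSE)

res$segmentation$aggregate$meanIoU
#> [1] 0.9967893

subset(res$trend, feature %in% c("Minor", "MinFeret", "Major"))
#>     feature            p
#> 10    Major 9.481455e-01
#> 11 MinFeret 3.920210e-07
#> 12    Minor 3.663208e-08

subset(res$diagnostics, feature == "Minor")[, 1:6]
#>    endpoint feature sensitivity specificity  f1     auroc
#> 12     >=F3   Minor           1   0.7586207 0.8 0.9482759
#> 28     >=F4   Minor           1   1.0000000 1.0 1.0000000
```

The pipeline generated 43 synthetic subjects (stage counts 5/11/13/11/3),
rendered speckle images, re-segmented them with the baseline Otsu+closing
segmenter (mean IoU 0.997 against truth), measured the 16 descriptors on
the segmented masks, and ran the staging statistics. The injected 10%
per-stage minor-axis thinning is recovered: `Minor` and `MinFeret` trend
strongly with stage (two-sided Jonckheere–Terpstra p ≈ 4e-8 and 4e-7)
while `Major`, whose generating distribution does not vary with stage,
shows none (p ≈ 0.95). `Minor` discriminates ≥F3 with AUROC 0.95 in the
`low_positive` orientation — lower values mean more advanced fibrosis.

Individual steps are available as plain functions: `binarize()`,
`largestParticle()`, `traceContour()`, `shapeFeatures()`,
`splitFrontRear()`, `roughnessScore()`, `segMetrics()`,
`jonckheereTerpstra()`, `rocAuc()`, and friends. See the methods vignette
(`vignettes/hepatomorph-methods.Rmd`) for the model, conventions and
parameter choices.

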