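# centrow

Central crop-row detection and navigation-line extraction for vision-guided
agricultural machinery.

Instead of segmenting every visible crop row and post-processing the result
(feature points, clustering, multi-line fitting), `centrow` follows the way a
human driver steers: find the **central crop row** and treat it directly as
the navigation line.  A lightweight U-shaped segmentation network predicts
three classes -- background, vegetation, central row -- where the central row
is annotated as a straight band of fixed 15-px width and the vegetation class
serves as auxiliary structural supervision.  The navigation line is then the
ordinary least-squares fit

    x = theta * y + b        (column regressed on row; well conditioned
                              for near-vertical rows)

to the pixel centers of the largest connected component of the predicted row
class.  Results are scored with pixel accuracy (PA), mean IoU (mIoU), angle
error (AE), line IoU (L_IoU: both lines rasterized as 15-px bands) and line
accuracy (LA: fraction of frames with AE < 5 deg and L_IoU > 50%).

The package covers the full pipeline:

* `renderScene()` / `renderDataset()` / `sampleSceneSpecs()` -- seeded
  synthetic field scenes with exact three-class ground truth and true line;
* `excessGreen()`, `binarizeLabA()`, `otsuThreshold()`, `selectBinary()` --
  vegetation binarization (ExG and Lab-a with Otsu);
* `lineFromEdgeMidpoints()`, `rasterizeLine()`, `composeLabels()` -- label
  construction at fixed 15-px width (plus the 2-class ablation);
* `rotateTriple()`, `lateralCropTriple()`, `randomAugment()` --
  geometry-consistent augmentation (rotation within +/-40 deg, lateral crop
  up to 60 px);
* `netConfig()`, `buildModel()`, `trainModel()`, `predictLabel()` -- the
  segmentation network (depthwise-separable blocks and ASPP skip modules,
  both toggleable) with seeded Adam training;
* `extractNavLine()`, `angleError()`, `lineIoU()`, `lineAccuracy()`,
  `evaluateModel()` -- line extraction and all metrics;
* `centrowMain()` / `inst/scripts/centrow` -- a command-line front end
  (`synth | annotate | train | eval | infer | budget`).

## Worked example

```r
library(centrow)

gt <- renderScene(sceneSpec(rowAngleDeg = 6, centralOffsetPx = -12, seed = 42))
gt
#> SceneGT: 256 x 256, 22.3% vegetation, 3864 row-band pixels, row angle 84.00 deg

veg <- selectBinary(gt@image, "auto")
cat("vegetation index:", attr(veg, "method"), "| cover:", round(mean(veg), 3))
#> vegetation index: lab_a | cover: 0.223

pred <- extractNavLine(gt@label)
pred
#> NavLine: x = theta*y + b  theta = 0.105037, b = 102.557, angle = 84.004 deg
cat("AE:", angleError(pred, gt@line), "deg | L_IoU:",
    lineIoU(pred, gt@line, dim(gt@label)))
#> AE: 0.00379443 deg | L_IoU: 0.9992236
```

The scene is a 256x256 field with rows tilted 6 degrees from vertical and
the central row shifted 12 px left of center.  The Lab-a index is selected
automatically and covers 22.3% of the image (the true vegetation fraction).
The line refitted from the ground-truth band reproduces the true line to
0.004 degrees with L_IoU 0.999 -- the fitting machinery is exact up to
rasterization.

Parameter budgets of the four architecture variants sharing the default
channel plan (standard / +ASPP / depthwise / depthwise+ASPP):

```r
sapply(ablationConfigs(), function(cfg) countParameters(buildModel(cfg)))
#>  base  aspp   dsc  full
#> 77272 91663 11852 26243
```

The depthwise blocks cut parameters by ~85%; ASPP adds multi-scale context
back at modest cost.  See the methods vignette
(`vignettes/central-crop-row.Rmd`) for how this channel plan is derived from
published budget totals and where it cannot match them.

## Command line

```sh
inst/scripts/centrow synth --n 8 --seed 1 --out dataset
inst/scripts/centrow train --data dataset --out model.rds --epochs 30 --size 96
inst/scripts/centrow eval  --data dataset --checkpoint model.rds --size 96
inst/scripts/centrow infer --image dataset/images/000.png --checkpoint model.rds
inst/scripts/centrow budget
```

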