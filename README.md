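# oratex

Texture-based screening of anomalous regions in oral-cavity
autofluorescence images.

Under blue-light excitation, normal oral mucosa fluoresces brightly while
dysplastic or otherwise lesional tissue absorbs the light and appears
dark. Devices built on this principle make lesions visible, but deciding
*which* dark patch merits a biopsy still requires an experienced
clinician. `oratex` is that clinician's first-pass assistant: it divides
an autofluorescence frame into 64 × 64-pixel super-pixels and classifies
each one as **standard** or **anomalous**, so flagged super-pixels can
guide biopsy site selection.

## The method

For an image *I* the pipeline runs:

1. **Device removal.** Frames often include the imaging device's circular
   aperture. Edges are found with the Deriche recursive gradient
   (smoothing kernel `s(x) = k(1 + α|x|)e^{−α|x|}`, antisymmetric
   derivative `d(x) = −c·x·e^{−α|x|}`, both exact second-order recursive
   filters) followed by Canny non-maximum suppression and hysteresis. A
   gradient-directed circular Hough transform then searches radii
   0.30–0.48 of the frame side; a hit scoring ≥ 0.35 (fraction of the
   circumference supported by radially-aligned edges) crops the frame to
   the aperture. No circle → the frame passes through unchanged.
2. **Quadtree division.** Fixed-depth subdivision to 64 × 64 leaves
   (a 1792 × 1792 frame → the 28 × 28 super-pixel grid). A super-pixel is
   labelled *anomalous* only if **every** pixel lies inside the
   clinician-delineated lesion; one standard pixel forces *standard*, so
   a flagged super-pixel is a safe biopsy target.
3. **GLCM texture features.** Per super-pixel, a 256 × 256 co-occurrence
   matrix `p(i, j)` at 0°, distance 1 (no requantisation), and ten
   Haralick features: angular second moment `Σp²`, contrast
   `Σ n²·P(|i−j| = n)`, correlation `(Σij·p − μxμy)/(σxσy)`, variance,
   inverse difference moment `Σ p/(1 + (i−j)²)`, sum average, sum
   variance, sum entropy, entropy `−Σ p·log p`, difference variance.
4. **Fisher-LDA feature ranking.** Each feature gets the univariate
   Mahalanobis separation `Δ² = (μ₁ − μ₂)² / C` with
   `C = (n₁C₁ + n₂C₂)/(n₁ + n₂)`; features are ranked descending and the
   top 8 feed the classifier.
5. **KNN with grouped cross-validation.** 1-nearest-neighbour on
   z-scored features; images are grouped, each fold trains on the other
   images of the test image's group. Sensitivity `TP/(TP+FN)`,
   specificity `TN/(TN+FP)` and accuracy are reported per fold and as
   mean ± sd.

Because no public archive of delineated clinical frames exists, the
package ships a seeded synthetic-scene generator (bright smooth
background, darker high-contrast lesion blobs, optional device aperture)
so every stage is testable and benchmarkable end to end.

## Worked example

```r
library(oratex)

## a ground-truthed benchmark: 10 scenes, 2 cross-validation groups
dir <- file.path(tempdir(), "demo")
man <- generate_benchmark(n_images = 10, n_groups = 2, seed = 1, dir = dir)

## full training phase: features -> LDA ranking -> grouped five-fold KNN
res <- run_training(attr(man, "path"))
head(res$ranking, 4)
#>   rank      feature     score
#> 1    1  correlation 430.32126
#> 2    2  sum_average  13.61775
#> 3    3 sum_variance  13.31709
#> 4    4          idm  13.26180
res$reports[["top8"]]
#> <fold_report: 10 folds, k = 1, 8 features>
#>   sensitivity  100.0% +/- 0.0%
#>   specificity  100.0% +/- 0.0%
#>   accuracy     100.0% +/- 0.0%
```

The ranking says the correlation feature separates the two classes by a
Mahalanobis distance of ≈ 430 on this benchmark — smooth background
windows are highly correlated at displacement 1, speckled lesion windows
are not. The fold report aggregates the ten folds (each scene tested
once, trained on the other scenes of its group): on synthetic scenes the
classes are cleanly separable and all three metrics reach 100%.

Device-present frames take the removal branch:

```r
sc <- generate_scene(scene_spec(seed = 31, size = 256,
                                device_circle = list()))
pre <- preprocess_image(sc$image, sc$mask)
pre$circle
#>   center_row center_col radius score
#> 1        128        128  102.8     1
pre$grid
#> <superpixel_grid 4 x 4 windows of 64 px (3 valid)>
```

The planted aperture (radius 102.4 at the frame centre) is recovered to
within half a pixel, the frame is cropped to its bounding square, and
only the 3 windows lying fully inside the aperture remain valid.

There is also a command-line interface (`inst/cli/oratex`) with
`synth`, `preprocess`, `train` and `test` subcommands wrapping the same
functions.

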