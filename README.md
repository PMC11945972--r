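# pupilloc

Real-time pupil center localization for blurred near-infrared eye images.

Eye trackers used for driver-fatigue monitoring capture near-infrared
periocular images that are often defocus-blurred (vibration, the eye leaving
the focal plane). Blur destroys edges and texture, so contour- and
gradient-based pupil detectors degrade badly. `pupilloc` implements a
double-constraint pipeline that uses only grayscale statistics and
region-level shape — no edge fitting anywhere — and therefore degrades
gracefully with blur:

1. **Grayscale constraint** — the pupil is the lowest-gray mode of the
   histogram. Threshold at the valley after that mode, binarize, and bound
   the dark mass by gray integral projection (per-row/per-column foreground
   counts, cut at 15% of each profile's maximum); expand the resulting
   rectangle by 1/20 of the image's long side.
2. **Geometric constraint** — inside the rough region: morphological
   opening, 8-connected components, hole filling (removes corneal glints),
   then screening by the pupil shape index

   $$w = \lambda_1\,\frac{I_{minor}}{I_{major}} +
         \lambda_2\,\frac{1}{1 + \Delta_{FittingError}},
   \qquad \lambda_1 = 0.6,\ \lambda_2 = 0.4,$$

   where $I_{minor}/I_{major}$ is the inertia ratio (eigenvalue ratio of the
   region's second-central-moment matrix) and $\Delta_{FittingError}$ the
   normalized area mismatch between the region and its moment-equivalent
   ellipse. The candidate with the largest $w$ wins.
3. **Moment locator** — on the winning region $S$, geometric moments
   $M_{ij} = \sum_{(x,y)\in S} x^i y^j$ give the sub-pixel center
   $(M_{10}/M_{00},\ M_{01}/M_{00})$ and the equivalent-circle radius
   $\sqrt{M_{00}/\pi}$ in one linear pass.

The package also ships a ground-truthed synthetic eye-scene generator
(defocus range 0–20 cm mapped to Gaussian blur σ of 0–6 px), an evaluation
harness (Euclidean error, 1%-of-long-side accuracy, blur-stratified), and a
command-line interface.

## Worked example

```r
library(pupilloc)

scene <- render_scene(scene_params(seed = 1, blur_sigma = 3))  # z = 10 cm
fit <- locate_pupil(scene$image)
fit
#> Pupil located at (319.701, 239.396), radius 45.09 px
#>   shape index w = 0.8390 (inertia ratio 0.7602, fit error 0.0446)
#>   threshold 39, 1 candidate region(s) in ROI [242, 401) x [166, 315)
localization_error(coef(fit)[1:2], c(scene$truth$x0, scene$truth$y0))
#> [1] 0.6740266
```

The located center is within 0.7 px of the generator's ground truth; the
high shape index says the winning region is uniform and elliptical, i.e.
confidently pupil-like. `plot(fit, scene$image)` draws the center cross and
the equivalent-radius circle over the image.

Batch evaluation:

```r
dir <- tempfile()
man <- generate_dataset(10, blur_levels = c(0, 5, 10, 15, 20),
                        out_dir = dir, seed = 42)
bm <- run_benchmark(file.path(dir, "manifest.csv"))
summary(bm)
#> Per-defocus-level results:
#>  defocus_z_cm  n mean_error_px accuracy_pct
#>             0 10      0.007684          100
#>             5 10      0.230987          100
#>            10 10      0.268770          100
#>            15 10      0.179566          100
#>            20 10      0.314264          100
#> Overall: n = 50 (0 failed), mean error 0.200 px, accuracy 100.00%, ...
```

Errors grow with defocus but stay well under the 1%-of-long-side
correctness threshold (6.4 px at 640×480).

From a shell, the same pipeline is available as subcommands:

```sh
Rscript inst/scripts/pupilloc simulate --n 10 --levels 0,10,20 --out-dir sim --seed 42
Rscript inst/scripts/pupilloc locate sim --out results.csv --annotate
Rscript inst/scripts/pupilloc eval --pred results.csv --manifest sim/manifest.csv --report report.json
```

## Scope

The package localizes the pupil center and equivalent radius only: no iris
or eyelid segmentation, no ellipse-parameter output as the primary result,
no camera capture or video loop. Synthetic scenes emulate defocus-blurred
near-infrared imagery; see the methods vignette
(`vignettes/pupil-localization-methods.Rmd`) for the model, parameter
choices, and what the synthetic benchmark does and does not demonstrate.
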