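# fibsemtools

Headless R tools for cleaning up and assessing cryogenic **serial FIB/SEM
image stacks** — the volumes built by alternating focused-ion-beam milling
with SEM imaging of each freshly exposed surface.  The package is aimed at
microscopists and image-analysis developers who need the three standard
pre-segmentation steps as scriptable, testable library functions rather than
GUI actions:

1. **Constrained stack alignment.**  Slice-to-slice registration by landmark
   matching and least squares over a *physically constrained* affine family
   `r' = A r + b`.  Only the degrees of freedom the acquisition can produce
   are fitted — e.g. `{translate, shear x, stretch y}` for FIB/SEM — and the
   disabled matrix entries are held at identity exactly, so a nonphysical
   rotation of the volume is structurally impossible.  Outliers are removed
   by a percentile trim or seeded RANSAC.
2. **Charge-artifact suppression.**  Given a label mask of charging centres,
   a row-by-row filter estimates each row's clean background from previously
   corrected rows, models the dark tails on both sides of every centre with
   a shifted logistic sigmoid `f(x) = a / (1 + exp(±(x − b)/c))`, and
   subtracts the fitted tails from unmasked pixels only (down and up passes,
   averaged).  Centres themselves are never modified.
3. **Resolution estimation by Fourier ring correlation (FRC).**  Two-image
   FRC with the 1/7 ≈ 0.143 threshold; one-image FRC by checkerboard
   subsampling with an instrument calibration (`d_2img = α·d_1img^β`) that
   maps it onto the two-image gold standard; tiled local-resolution maps and
   a Kruskal–Wallis check that the tile size does not bias the estimate.

A seeded synthetic-data module (`make_textured_image`,
`make_misaligned_stack`, `make_charging_image`, `make_bandlimited_pair`)
generates inputs with recorded ground truth so every stage is testable
without downloading microscope data.  I/O covers multipage TIFF (including
lossless float32) and MRC2014 stacks, PNG/TIFF masks, JSON results and CSV
resolution tables.

## Worked example

```r
library(fibsemtools)

## 1. recover a known 0.15 x-shear with the constrained aligner
img     <- make_textured_image(c(512, 512), seed = 0)
sheared <- apply_transform(img, affine2d(matrix(c(1, 0, 0.15, 1), 2, 2)))
spec    <- transform_spec(translate = TRUE, shear_x = TRUE)
matches <- detect_and_match(img, sheared)
inliers <- filter_matches_ransac(matches, spec, inlier_tol_px = 2,
                                 n_iter = 1000, seed = 0)
fit_constrained_transform(inliers, spec)
#> <affine2d> A = [ 1 0.14999 ; 0 1 ], b = ( -0.00658493 , 0.00772201 )
```

The shear is recovered to four decimals (0.14999 vs 0.15) and the entries
the family disables (`a11`, `a21`, `a22`) are identity *exactly* — this is
the constraint, not luck.

```r
## 2. suppress charging tails around a labelled centre
gen  <- make_charging_image(
  shape = c(128, 256),
  centers = data.frame(x = 128, y = 64, rx = 60, ry = 12),
  tail_params = list(list(left = c(-40, 20), right = c(-50, 30))),
  noise_sigma = 2, seed = 0)
filt <- chafer_filter(gen$image, gen$mask)
background_std_report(gen$image, filt, gen$mask, radius_px = 50)
#> background sd near centre: 4.69 -> 2.00 (57% reduction)
```

The standard deviation of the background within 50 px of the centre drops
by 57%; the residual 2.00 is the image noise floor, which the filter
deliberately leaves alone (it removes the artifact, not the noise).

```r
## 3. FRC resolution: two-image gold standard vs one-image estimate
pair <- make_bandlimited_pair(c(512, 512), cutoff_norm = 0.5, snr = 5, seed = 0)
resolution_from_curve(compute_frc(pair$img_a, pair$img_b), pixel_size_nm = 6.745)
#> <resolution_result> f_crossing = 0.5073, resolution = 3.942 px = 26.59 nm [ok]
one_image_frc(pair$img_a, pixel_size_nm = 6.745)
#> <resolution_result> f_crossing = 0.9555, resolution = 2.093 px = 14.12 nm [ok]
tiled_resolution(pair$img_a, 128)
#> <resolution_map> tile 128 px, 16 tiles included: median 2.087 px (mean 2.071, sd 0.047)
```

The two-image crossing lands on the generator's known cutoff (0.507 vs
0.5).  The uncalibrated one-image estimate is systematically *finer*
(2.09 px vs 3.94 px) — that bias is inherent to checkerboard subsampling and
is what `fit_calibration()` absorbs when repeated image pairs at several
pixel sizes are available.

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/fibsemtools`:

```sh
Rscript inst/cli/fibsemtools align --input stack.tif \
    --spec translate,shear_x,stretch_y --filter ransac --seed 0 \
    --output aligned.tif --transforms-json transforms.json
Rscript inst/cli/fibsemtools chafer --input slice.tif --mask mask.tif \
    --output filtered.tif --report report.json
Rscript inst/cli/fibsemtools frc compare-tiles --input img.tif --tiles 128,256,512
Rscript inst/cli/fibsemtools simulate bandlimited --seed 1 --out sim/
```

Each run echoes its effective configuration to `*_config.json` beside the
outputs.

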