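---
title: "Methods: constrained stack alignment, charge-tail suppression and one-image FRC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained stack alignment, charge-tail suppression and one-image FRC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibsemtools)
```

Serial FIB/SEM builds a volume by alternating ion-beam milling with SEM
imaging of each freshly exposed face.  Three instrument effects dominate the
clean-up that has to happen before segmentation: slice-to-slice misalignment
(drift, milling-placement shear), charging artifacts around insulating
features, and the need for a quantitative per-image resolution estimate to
judge acquisition settings.  This vignette describes the models behind the
three tools, the tunable parameters, what the synthetic generators do and do
not emulate, and the numerical choices made where the design was open.

## Constrained stack alignment

The registration model is a 2D affine map `r' = A r + b` acting on pixel
coordinates (x = column = fast-scan direction, y = row = slow-scan, origin at
the top-left, 0-based).  The key idea is that the *family* of maps is
restricted to the degrees of freedom the acquisition physics can actually
produce.  A line-scanned serial image can drift (translation), shear along x
(milling-placement error accumulating down the slow-scan axis), and stretch
along y (milling-thickness/scan-rate mismatch); it cannot rotate.  An
unconstrained fit on matches concentrated in feature-rich regions happily
introduces a rotation that aligns those regions while twisting the rest of
the volume, so entries not enabled by the chosen family are held at their
identity values *exactly*, by construction of the design matrix, not by
penalization.

Supported families and solvers:

* any subset of `{translate, shear_x, shear_y, stretch_x, stretch_y,
  scale_uniform}`: the residual is linear in the free parameters, so the
  least-squares problem is solved exactly by QR on the stacked x/y
  equations;
* `{translate?, rotate, scale_uniform?}`: closed-form 2D Procrustes
  (centroid removal, `atan2` angle, optional scale);
* `affine`: all six degrees of freedom by the same linear solver.

Mixing `rotate` with shear/stretch is rejected: those families have no
closed-form solution, and physically a rotating modality is exactly the case
where shear should not be fitted.

Landmarks come from a deterministic corner pipeline: Shi-Tomasi response
(minimum eigenvalue of the smoothed structure tensor, smoothing scale 1.2 px,
integration scale 2 px), strict 8-neighbour non-maximum suppression, up to
1500 keypoints per image, 15x15 mean-removed L2-normalized patch
descriptors, nearest-neighbour matching with a Lowe ratio test at 0.75 and a
mutual-nearest-neighbour check.  Everything is deterministic for fixed
inputs, which makes alignment runs reproducible end to end.

Outlier handling offers the two standard options.  The percentile filter
keeps matches whose displacement components both lie inside the
`[q, 100 - q]` percentile interval (default `q = 5`); it is fast but assumes
a majority of consistent matches per component.  RANSAC (default: 2 px
inlier tolerance, 1000 iterations, minimal sample `max(3,
ceil(n_params / 2))`, explicit seed, final refit on all inliers) is slower
but robust when matches are scarce.  The percentile interval is applied per
displacement component: the simplest reproducible reading of a percentile
trim, stated here because other conventions (magnitude-based, score-based)
exist.

Alignment proceeds sequentially from slice 1: each pairwise fit maps slice
`k+1` into slice `k`'s frame, the running composition maps every slice into
the reference frame, and each slice is resampled **once** through its
cumulative transform (bilinear, median fill) to avoid accumulating
interpolation blur.  A pair with too few matches reuses the previous
pairwise transform (identity for the first pair) and is flagged in the
result rather than raising: a single featureless slice should degrade, not
destroy, a long acquisition.

## Charge-artifact suppression

Charging appears as dark tails smeared along the fast-scan direction on both
sides of an insulating feature.  The filter requires a label mask of the
charging centres (manual or learned segmentation; producing it is out of
scope) and restores the surroundings while leaving the centres untouched.

Working row by row, the clean signal under the current row is estimated as
the per-column mean of the `n_lines_average` (default 5) previously
*corrected* rows in the pass direction, excluding masked pixels column-wise;
columns masked in all contributing rows fall back to the row's mean valid
background.  The difference between the current row and this estimate
isolates the charging contribution.  Each side of every labelled segment is
then fitted with a three-parameter shifted logistic (Fermi-Dirac) curve

    f(x) = a / (1 + exp(s (x - b) / c)),   s = -1 (left), +1 (right)

which saturates to the amplitude `a` next to the centre and decays to zero
away from it -- the empirically right shape for these tails, and much more
stable in optimization than Gaussian or exponential alternatives, which are
deliberately not offered.  Fits use Levenberg-Marquardt with
geometry-derived starting values (amplitude from the 5 valid pixels adjacent
to the segment, centre at the segment boundary, width `max(2, segment
length / 4)`).  A window shorter than 4 valid pixels, or a non-converged
fit, skips that side (counted in the fit log, never an error); an exactly
flat difference signal short-circuits to a zero-amplitude tail.  Fitted
curves are subtracted from unmasked pixels only, within windows bounded by
neighbouring segments so tails never leak across another centre.

Two passes are run, top-to-bottom and bottom-to-top, and the final image is
their arithmetic mean.  Sequential in-place alternatives exist; averaging is
symmetric, deterministic, and covers each pass's first row by the other
pass.  The whole filter is deterministic, and an empty mask returns the
input bitwise.

Effectiveness is quantified by `background_std_report`: the standard
deviation of unmasked intensities within a Chebyshev radius (default 50 px)
of any labelled pixel, before vs after.  On the synthetic
elongated-droplet fixture the reduction is about 57%; the residual floor is
the image noise, which the filter, by design, does not touch.

## Resolution estimation by Fourier ring correlation

The two-image FRC correlates two registered images of one field of view over
rings of spatial frequency,

    corr(q) = Re{ sum F1 conj(F2) } / sqrt( sum |F1|^2 sum |F2|^2 ),

with frequencies normalized so the outermost computed ring is 1 (a 2-pixel
period).  Rings are one radial DFT bin wide (`round(radius)`), and a
separable Hann taper is applied before the FFT to suppress edge leakage;
both are standard FRC practice and the numerator keeps the real part, not
the magnitude, so anticorrelation is visible.  The resolution is read off
where the curve first drops below the threshold (default 1/7, about 0.143,
stored at full precision), with linear interpolation between the bracketing
rings; `resolution_px = 2 / f_crossing`.  Curves that never cross are
flagged `at-limit` (`f_crossing = 1`), curves already below the threshold at
the first ring `unresolved`.

When only one image exists, its four checkerboard parity sub-images are
formed and the FRC is computed between the two diagonal pairs (even-even vs
odd-odd, even-odd vs odd-even) and averaged -- both diagonals are used to
halve the variance and keep the result deterministic.  The sub-images are
treated as contiguous grids at the original pixel pitch.  This convention is
deliberate and biased: the diagonal pairs are offset by half a sub-pixel, so
their correlation decays geometrically with frequency and the one-image
curve reports systematically *finer* resolution than the two-image gold
standard.  That bias is instrument- and noise-dependent, which is exactly
why the method ships with a calibration step: repeated image pairs at
several pixel sizes give matched `(d_1img, d_2img)` points, and a
two-parameter power law `d_2img = alpha d_1img^beta` is fitted in log-log
space.  A power law is the simplest monotone two-parameter family that a
three-pixel-size calibration set can support; the family is recorded on the
model, applying it outside the fitted domain sets a warning flag, and
non-monotone calibration data are flagged rather than rejected.

Local resolution maps tile the image with non-overlapping squares anchored
top-left (partial edge tiles dropped, tiles more than half masked excluded),
run the one-image FRC per tile, and summarize mean/sd/median.
`compare_tile_sizes` checks the tiling choice itself: on a homogeneous image
the per-tile distributions for different tile sizes should share a median,
tested with the Kruskal-Wallis H-test.

## Synthetic data: what it does and does not show

Every generator is a pure function of its parameters and an explicit seed
(bitwise reproducible, no global RNG state leaks), and returns a ground
truth record alongside the data.

* `make_textured_image`: smoothed random blobs (default density 0.005 per
  pixel, radius 2.5 px) plus 5% Gaussian noise -- enough distinctive corners
  that the detector finds hundreds of landmarks on a 512x512 frame.
* `make_misaligned_stack`: the texture, evolved by a 2% smooth perturbation
  per slice (consecutive physical sections are similar but not identical),
  resampled through the inverse of a known cumulative transform.
* `make_charging_image`: flat background 100, dark ellipses (depth -50),
  exact sigmoid tails per row and side, Gaussian noise (sd 2).  The test
  fixture uses one elongated centre (radii 60 x 12 px in a 128 x 256 field)
  with asymmetric tails (amplitudes -40/-50, widths 20/30 px), chosen so
  the artifact-to-noise ratio sits in the strong-charging regime where
  row-wise restoration is actually needed; the measured background-std
  reduction there is about 57%.
* `make_bandlimited_pair`: white noise hard low-passed at a known fraction
  of Nyquist, unit-sd, plus two independent noise realizations at amplitude
  SNR 5 (a representative mid-range SEM value).  The hard cutoff makes the
  two-image FRC crossing a sharp, known target (0.5 by default).

These fixtures validate the estimators against known ground truth; they do
not reproduce real SEM physics.  In particular the noise is Gaussian and
pixel-independent (no Poisson component, no detector correlations), the
charging tails follow the fitted model family exactly (so tail-recovery
tests show correctness of the optimizer, not model adequacy on real tails),
there is no curtaining, and the band-limited spectrum is flat below its
cutoff rather than decaying.  Passing tests therefore demonstrate that each
algorithm does what its model claims under that model's assumptions; the
published behaviour on archived EMPIAR stacks (e.g. roughly 60% / 58%
background-std reductions on yeast and brain data) additionally depends on
the hand segmentation used and can only be checked with those stacks
present.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: rank-deficient landmark systems
and singular warps raise; empty match sets filter with an informative error;
all-zero images have no defined FRC normalization and raise; exponent
clamping keeps sigmoid evaluation finite; integer-policy writes refuse
non-finite values rather than clip.  Ties in non-maximum suppression are
broken strictly (plateaus yield no keypoint), RANSAC keeps the first best
consensus, and the FRC crossing takes the *first* ring below threshold.

The test and demonstration sizes -- 512x512 single-pair alignment, 10-slice
256x256 stacks, a 128x256 charging field, 1024x1024 tiled FRC with tile
sizes 128/256/512 -- were chosen as the smallest sizes at which each
statistic is comfortably stable (hundreds of landmarks per pair, 84 tiles
across the three tilings), and they keep the whole suite fast on a single
CPU.

## Known limitations

Alignment assumes enough texture for landmark matching; long featureless
runs degrade to transform reuse.  The charge filter assumes dark tails along
x around labelled centres (bright or mixed-polarity charging is untested)
and depends on the quality of the provided segmentation.  The one-image FRC
is only comparable to the two-image gold standard through an
instrument-specific calibration, and the shipped power-law family is a
modelling choice, not a physical law.  MRC support covers the common modes
(0, 1, 2, 6) of single-volume files; OME-Zarr, RGB data and anisotropic
in-plane pixels are out of scope.
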