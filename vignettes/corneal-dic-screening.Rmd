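---
title: "Methods: incremental DIC and biomechanical screening of air-puff corneal sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incremental DIC and biomechanical screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Non-contact tonometry films a horizontal cross-section of the cornea while
a calibrated air puff pushes it inward and lets it spring back: about 140
frames covering roughly 30 ms. In the earliest, *forme fruste* stage of
keratoconus (FFKC) the corneal surface still looks normal on tomography,
but the tissue is already mechanically weaker; the hypothesis behind this
package is that the weakness shows up in how the whole corneal bulk moves
and strains over the entire deformation cycle, not in any single surface
landmark. airDIC therefore measures the full-field motion of the corneal
band through the sequence, condenses it into per-exam time curves, and asks
standard classifiers to separate FFKC from normal exams.

The pipeline has five stages, each an exported function:

1. **Tracking** (`track_incremental`): incremental subset-based digital
   image correlation (DIC) gives accumulated horizontal/vertical
   displacements U, V on a measurement grid.
2. **Strains** (`pointwise_ls_strain`): Cauchy components
   $\varepsilon_{xx}, \varepsilon_{yy}, \gamma_{xy}$ from local
   least-squares plane fits of the displacement field.
3. **Rates** (`temporal_rate`, `compute_rates`): velocities UR, VR (px/ms)
   and strain rates (1/ms) by finite differences in time.
4. **Evolution curves** (`extract_evolution_curves`): per frame, the
   maximum and the mean of $|V|, |\gamma_{xy}|, |VR|, |\gamma_{xy}R|$ over
   the valid grid — eight scalar curves per exam.
5. **Classification** (`train_models`, `evaluate_bundle`): Gaussian Naive
   Bayes, Random Forest, their soft-voting ensemble, and a ridge-penalized
   logistic regression on the flattened curves, with an 80/20 stratified
   split, 5-fold cross-validation and confusion-matrix/ROC reporting.

Because no clinical sequences are distributable, a synthetic generator
(`sim_config`, `render_sequence`, `generate_cohort`) with exact analytic
ground truth stands in for the device, and every stage is validated against
that ground truth.

## The DIC engine

Matching uses the zero-normalized sum of squared differences (ZNSSD): for a
reference subset $f$ and candidate window $g$,
$$C(\mathbf d) = \sum_i \left( \frac{f_i - \bar f}{\sigma_f} -
  \frac{g_i(\mathbf d) - \bar g}{\sigma_g} \right)^2,$$
which is invariant to affine intensity changes $aI+b$; reported quality is
the equivalent ZNCC. Each increment is found by an exhaustive integer
search (radius 6 px by default) followed by translation-only Gauss–Newton
refinement on a prefiltered cubic B-spline interpolant of the current
frame, with a paraboloid fit of the 3×3 correlation surface as a fallback
when the iteration does not converge. A translation-only shape function per
*increment* is the core modelling assumption of the incremental method: at
140 frames / 30 ms the per-frame deformation is a small fraction of a
pixel, so higher-order subset shape terms are unidentifiable and
unnecessary.

Two numerical choices matter for accuracy over long sequences and were made
after measuring the alternatives on synthetic data (the package's analytic
oracle):

* **Interpolation.** Cubic *B-spline* interpolation (recursive prefilter,
  then the smooth spline basis) replaces the more common cubic-convolution
  kernel. On sharp speckle the S-curve bias — the systematic pull of
  subpixel estimates toward integer positions — is roughly an order of
  magnitude smaller for the prefiltered spline, and in an incremental
  scheme that bias otherwise accumulates across a hundred-plus frames.
* **Reference anchoring.** The incremental reference subset for frame pair
  $(t-1, t)$ is extracted at the *integer pixel nearest* the point's
  accumulated position, so the reference is always raw pixel values and is
  never itself resampled. Resampling the reference at sub-pixel positions
  imposes a coherent, phase-dependent smoothing whose matching bias
  accumulates monotonically during the inward stroke of the puff;
  anchoring eliminates it. The price is that the measured increment
  belongs to the anchor rather than to the tracked point (offset ≤ 0.5
  px); this is compensated to first order with a local plane fit of the
  increment field over neighbouring grid points — the same smoothness
  assumption the strain stage makes. The residual error is second order in
  the offset and, by measurement, negligible.

Points whose ZNCC quality drops below 0.8 (default), or whose optimum sits
on the search border, are invalidated from that frame onward; their
increments are in-filled with the median of valid neighbours within one
grid step, and the in-fill is flagged in the output (`filled`), never
silent. More than 50% invalid points at any frame aborts the exam with the
frame index.

Region of interest: Otsu threshold on frame 0, largest connected component,
morphological closing — adequate for a bright band on a dark background; a
user mask can replace it. The measurement grid is a row-major lattice
(step 8 px) of points whose whole subset (25 px default) fits inside the
dilated band.

## Strain and rate estimation

For each point and frame, displacements of the valid neighbours within a
window (default radius = 2 grid steps, about a 5×5 stencil) are fitted with
$u = a_0 + a_1 x + a_2 y$, $v = b_0 + b_1 x + b_2 y$ by ordinary least
squares, and $\varepsilon_{xx} = a_1$, $\varepsilon_{yy} = b_2$,
$\gamma_{xy} = a_2 + b_1$. $\gamma_{xy}$ is the *engineering* shear, the
standard DIC convention for these components; the tensor half-shear is one
flag away. The plane fit is exact on affine fields, invariant to rigid
translation, and requires at least 6 non-collinear valid neighbours (a
single-row grid is rank-deficient and yields invalid strains, by design).
Its known cost is smoothing bias where the displacement field has spatial
curvature; at the default window and the simulator's bump width this is a
few percent of the peak shear, which is why the shear-accuracy check uses a
5% tolerance.

Rates use central differences at interior frames and one-sided differences
at the two ends — linear, endpoint-complete, exact for series linear in
time. Smoothed differentiation was rejected to keep the operator linear and
reproducible. Velocities are px/ms (mm/ms when a scale is supplied);
strains are dimensionless so their rates are 1/ms.

Whole-eye motion compensation (`compensate_rigid_motion`) subtracts the
per-frame mean translation of a peripheral band (outermost 10% of points by
distance from the apex, where the puff response has decayed). It is **off
by default**: the synthetic default has no drift, and on real data the
decision belongs to the analyst.

## Features and classifiers

Curves are computed on magnitudes $|Q|$: the sign of V is an orientation
convention, and a signed maximum is dominated by noise polarity; a `signed`
switch restores raw statistics. Invalid grid points are excluded, not
imputed. The default feature set keeps only the four *ave-* curves — means
are far less noise-sensitive than maxima, and dropping the max- curves
measurably improves separation — over all T frames: 4 × 140 = 560 columns
named `curve@frame`.

Model choices where the underlying references are generic: Gaussian NB with
a variance floor of $10^{-9}\times$ the largest column variance (features
are continuous; the floor guards degenerate class-conditionals); Random
Forest with 100 trees and library defaults under a fixed seed; soft voting
as the arithmetic mean of NB and RF class-1 probabilities (a hard vote of
two members is degenerate and cannot produce a continuous score for ROC
analysis); ridge logistic regression (penalty 1/n) on z-scored features.
The standardizer is fitted on training rows only and reused everywhere —
a leakage test asserts this. Hard labels use the 0.5 threshold throughout.

Evaluation reports accuracy, precision, recall, F1, sensitivity,
specificity from the confusion matrix, and AUC from the continuous scores.
For classifier scores the ROC direction is fixed (higher = FFKC), so a
model below chance honestly reports AUC < 0.5; for raw parameters of
unknown polarity `roc_auc` auto-orients and reports the direction, with the
optimal cut-off at the maximum Youden index $J = \text{sens} +
\text{spec} - 1$ (the criterion is configurable; Youden is the field
default). The companion `reconstruct_confusion` enumerates all integer
confusion matrices consistent with rounded published metrics — the tool
used to check printed performance tables for internal consistency (one
published validation row is provably inconsistent and is flagged as an
empty solution set). Published-table comparisons round half away from
zero to 2 decimals, matching clinical-table convention.

The summary-statistic tests mirror the published demographics analysis:
pooled-variance Student t (with equal n it reproduces the printed CCT and
bIOP statistics to 2 dp, which Welch does not), and the uncorrected Pearson
chi-square (the Yates-corrected value contradicts the printed gender
statistic; the uncorrected one matches).

## What the simulator emulates — and what it does not

One synthetic exam is a bright corneal band (quadratic centreline, uniform
thickness, default 40 px) on a dark background, speckled with dark disks,
deformed by the analytic field
$$V(x, t) = -a(t)\,B(x) + \text{drift}_y t, \qquad
  U(x, t) = -c\,a(t)\,B'(x) + \text{drift}_x t,$$
where $B(x)$ is a Gaussian bump (width `spatial_sigma`, default 60 px,
amplitude `amplitude_peak`) optionally plus a second, narrower bump — the
focal weakening; $a(t)$ rises as $(t/t_{peak})^2$ and decays as
$\exp(-(t-t_{peak})/\tau)$ with the viscoelastic lag $\tau$
(`recovery_lag`); and the small lateral coupling $c$ gives a nonzero
$\varepsilon_{xx}$. All strains and rates follow in closed form, making the
generator a machine-precision oracle for every downstream stage. The kink
of $a(t)$ at the peak uses the decaying branch's derivative.

Two generator design points deserve emphasis:

* **Exact image formation.** The texture is an analytic function of
  material coordinates (disks with a logistic edge of scale 0.7 px on the
  smooth band profile), so frame $t$ is rendered by *exactly evaluating*
  the warped texture at each pixel, after a fixed-point inversion of the
  forward map. No raster is ever resampled during rendering; the frames
  are what an ideal camera would record of a continuously moving scene,
  and all interpolation error in the benchmark is attributable to the DIC
  engine. Sensor noise is i.i.d. Gaussian (default sd 2 gray levels),
  clipped to [0, 255], and frames are quantized to the 16-bit gray grid so
  TIFF round trips are bit-exact.
* **Fixture defaults are declared, not physiological claims.** The device
  frame geometry is not public, so 576×200 px, 140 frames, 30/139 ms frame
  interval are package fixtures. The class-conditional priors of
  `cohort_priors()` place the FFKC signal in pulse amplitude (7.0 vs 8.0
  px, sd 1.2), recovery lag (12 vs 24 frames — the doubled lag encodes the
  stronger viscoelastic asymmetry of weakened tissue), peak timing (70 vs
  72) and a focal weakening bump (0 vs 1.0 px); fast-mode curves carry 15%
  relative measurement noise standing in for DIC estimation error. The
  priors were calibrated once against the full pipeline and then frozen;
  they are documented fixture values.

What passing tests on this generator **do not** show: real corneal
sequences have depth-dependent deformation across the band thickness,
correlated speckle from scattering, illumination drift, blinks and
alignment artefacts, and — most importantly — a true FFKC signal of
unknown form and size. Synthetic recovery demonstrates that the
*measurement chain is faithful* (fields in, fields out) and that the
*ensemble can recover a planted class difference of plausible shape*; it
cannot certify clinical sensitivity or specificity.

## Validation scale and numerical conventions

The shipped checks run at desk scale, chosen so the whole suite stays in
minutes on one CPU: single-exam oracle comparisons use the full 576×200 ×
140-frame geometry (about 120 grid points); cohort-level checks use 50+50
exams in fast mode (curves from ground truth) over 10 seeds; the
ROC/Mann–Whitney equivalence sweeps 1000 random instances of up to 30
points. Degenerate inputs have defined behaviour rather than crashes: flat
subsets are flagged invalid, single-class evaluations report AUC as
missing, zero denominators yield missing metrics, a frame losing all valid
points is an error naming the frame, and every stochastic path is
reproducible from a single integer seed (sequences bit-identically so).

Coordinates are 0-based pixels with x rightward and y downward; V is
positive downward; gray values live in [0, 255]; velocities are px/ms
unless a mm/px scale is given.

## Known limitations

* Translation-only increments cannot represent large per-frame rotations
  or strains; the method is specific to the small-increment regime of
  air-puff imaging.
* The pointwise least-squares strain window trades noise for smoothing
  bias; fields with curvature at the scale of the window are attenuated by
  a few percent.
* The incremental chain still accumulates a slow random walk of
  per-increment errors; on noise-free drifting sequences the field-mean
  position error after 140 frames is of order 0.1 px. Applications needing
  absolute sub-0.05-px accumulated accuracy should re-anchor against frame
  0, which this package deliberately does not do (it would break on large
  total deformation).
* The Gaussian NB treats the 560 columns as conditionally independent,
  which is plainly false for smooth curves; it is kept as a deliberately
  weak-but-different ensemble member.
* The classifiers see flattened curves only; spatial *patterns* of the
  fields (beyond the max/ave reduction) are out of scope.

## A minimal end-to-end run

```{r example}
library(airDIC)

# one synthetic exam, tracked and reduced to curves
cfg <- sim_config(amplitude_peak = 8, noise_sd = 2, seed = 3)
rs <- render_sequence(cfg)
grid <- build_grid(corneal_roi(rs$sequence$frames[[1]]))
field <- track_incremental(rs$sequence, grid)
curves <- curves_from_field(field)

# a labeled cohort in fast mode, classified
cohort <- generate_cohort(50, 50, seed = 1)
fm <- assemble_feature_matrix(cohort)
split <- split_cohort(fm, seed = 1)
bundle <- train_models(split$train, seed = 1)
evaluate_bundle(bundle, split$validation)
timepoint_sweep(cohort, k_list = c(1, 5, 10, 35, 70, 140), seed = 1)
```
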