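---
title: "Methods: tendon DTI reliability analysis with synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tendon DTI reliability analysis with synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tendondti` implements a complete, testable pipeline for assessing how
reliably diffusion tensor imaging (DTI) characterises tendon microstructure:
inter-rater reliability of manual segmentations and test-retest repeatability
across scan sessions, quantified by intraclass correlations (ICCs) from
linear mixed models. Because tendon MRI data are rarely shareable, the
package ships a synthetic phantom cohort generator that emulates the study
design end to end, so every stage — region geometry, tensor fitting, metric
extraction, reliability statistics — can be exercised and validated without
any image download.

This vignette records the models, the tunable parameters, the numerical
choices, and the design decisions that were genuinely open.

## The measurement model

DTI models water diffusion per voxel as a symmetric positive 3x3 tensor
$D$. The acquired signal under diffusion weighting $b$ (s/mm$^2$) along unit
direction $g$ is

$$S(b, g) = S_0 \, e^{-b\, g^\top D g},$$

and the scalar metrics of interest are the sorted eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ (axial and radial diffusivities),
mean diffusivity $\mathrm{MD} = (\lambda_1+\lambda_2+\lambda_3)/3$, and
fractional anisotropy

$$\mathrm{FA} = \sqrt{\tfrac{3}{2}}\,
  \frac{\sqrt{\sum_i (\lambda_i - \mathrm{MD})^2}}{\sqrt{\sum_i \lambda_i^2}} .$$

Healthy tendon is strongly ordered collagen: high $\lambda_1$ along the
fibre axis, low radial diffusivities, FA well above muscle. Pathological
tendon (tendinopathy, or the harvest-site defect of a bone-patellar
tendon-bone [BPTB] graft) has looser, less organised collagen: higher
diffusivities and lower FA.

The emulated acquisition uses one shell at $b = 800$ s/mm$^2$ with 30
directions plus 4 unweighted volumes, a 1.4 x 1.4 x 3.0 mm$^3$ DTI grid,
and 0.5 mm isotropic anatomical masks — the regime in which tendon DTI
studies operate. Directions are a deterministic golden-angle hemisphere
spiral, which is well conditioned (design rank 7) without needing an
optimised gradient table.

## Tensor fitting

`fit_tensor_loglinear()` solves the log-linearised model
$\ln S = \ln S_0 - b\,g^\top D g$ per voxel: an ordinary least-squares pass
followed by one reweighted pass with weights equal to the squared predicted
signal, which corrects the variance distortion introduced by the log
transform. Non-positive signals (possible only in pathological inputs; the
Rician magnitude model never produces them) are clamped to a small epsilon
and recorded.

`fit_tensor_nonlinear()` then minimises the un-logged least-squares
objective with per-voxel Levenberg-Marquardt (via `minpack.lm`), started at
the log-linear estimate. Numerical choices:

* convergence when the relative objective decrease falls below `1e-10`, or
  100 iterations; voxels hitting the iteration cap are flagged invalid
  rather than aborting the run;
* the damped iteration is monotone, so the objective never exceeds the
  initialiser's; a safety net keeps the initialiser if numerical trouble
  ever produced a worse value;
* an optional positivity mode re-parameterises $D$ through its Cholesky
  factor $D = LL^\top$, forcing non-negative eigenvalues. Both constrained
  and unconstrained modes are provided because published tendon pipelines
  differ in whether they constrain the fit.

Noise can push unconstrained eigenvalue estimates negative. Such voxels are
kept in the maps but flagged non-physical, and region statistics use only
valid, physical voxels. An all-zero tensor has undefined FA and is flagged
invalid.

## Region geometry

The tendon mask (segmented at anatomical resolution) is partitioned into
six regions:

* **medial / central / lateral** — per transverse slice, the greatest
  cross-sectional diameter is found and trisected; boundaries perpendicular
  to the diameter axis at 1/3 and 2/3 of its extent define three full-length
  regions of equal width;
* **proximal / distal** — the occupied slices are halved; an odd slice
  count puts the middle slice in *both* regions;
* **whole** — everything.

Design decisions where the procedure was genuinely open:

* *Greatest diameter* is interpreted as the longest chord between
  boundary-voxel centres of the slice's largest connected component,
  computed from the convex hull of the boundary points. Distance ties are
  broken by the lexicographically smallest endpoint pair, making the result
  deterministic. (With tied diameters no translation-invariant tie-break
  can be mirror-equivariant, which is why the medial/lateral mirror-swap
  property is exact only for slices with a unique diameter.)
* Voxels projecting exactly onto a cut point go to **central**; slices with
  an extent under ~3 in-plane voxels along the diameter axis are assigned
  entirely to central, so degenerate end slices never produce empty edge
  regions.
* Which end of the diameter axis is medial is resolved from mask metadata
  (`limb_side`, `medial_direction`) and is required, never guessed.
* Volume is voxel count x voxel volume, reported in cm$^3$.
* Masks are downsampled to the DTI grid by partial-volume occupancy: a DTI
  voxel is kept when at least half its volume (threshold configurable,
  ties included) is covered by mask. Trisection labels transfer to kept
  voxels by majority occupancy among the three label masks (ties prefer
  central); proximal/distal are re-derived from the slice rule on the DTI
  grid.
* Erosion by one boundary pixel is **2D in-plane** with a 4-connected
  structuring element: with 3 mm slices, 3D erosion would delete the first
  and last slices outright.

Intratendinous calcifications are excluded by plain set difference before
any region derivation.

## The synthetic cohort

`simulate_cohort()` emulates the study design: `n_subjects` participants
(default 10, half tendinopathy and half BPTB), each contributing a
pathological and a contralateral limb; two scan sessions within a week; two
raters segmenting session 1 and rater 1 segmenting session 2.

**Geometry.** Each tendon is a curved elliptic cylinder: ~25 slices at
0.5 mm, in-plane semi-axes 7.5 mm (medial-lateral) and 4 mm
(antero-posterior), a 2 mm in-plane bow, and per-subject log-normal (8% CV)
semi-axis variation. This mimics the proportions of a patellar tendon free
segment; it does not attempt the patellar/tibial attachment flare.

**Tissue.** Healthy tendon defaults to
$\lambda = (1.05, 0.55, 0.48)\times 10^{-3}$ mm$^2$/s, i.e.
MD $= 0.693 \times 10^{-3}$ mm$^2$/s and FA $\approx 0.42$, consistent with
reported in vivo patellar tendon values. Pathological classes scale
diffusivities up (x1.2 tendinopathy, x1.3 BPTB) and mix the tensor toward
isotropy (25% / 30%), lowering FA — the direction of change reported for
pathological tendons. The principal eigenvector follows the mask
centreline.

**Raters.** A simulated rater perturbs the mask's signed distance field
with a smooth zero-mean Gaussian random field (correlation length 2 mm,
amplitude default 0.5 mm) and re-thresholds at zero, keeping the largest
connected component. Spatially correlated perturbation was chosen over
independent voxel flips because human raters disagree along boundary
stretches, not on isolated voxels.

**Sessions and the ICC ground truth.** Between-subject and between-session
variation enter as a subject random effect plus a session fluctuation on
the log-diffusivity scale (and on the isotropy-mixing scale for FA), with
the session variance back-computed from the requested test-retest ICC
$\rho_t$: $\sigma_e = \sigma_u\sqrt{(1-\rho_t)/\rho_t}$. The package also
provides a metric-level mode (`level = "metric"`) that draws region means
directly from the full three-component decomposition
(subject + session + rater), for which the requested retest and inter-rater
ICCs hold exactly in expectation. This analytic mode is what the
ICC-recovery and bootstrap-coverage calibration tests use; the image mode
realises the same structure only approximately (rater variance arises from
geometry jitter, and region means are mildly nonlinear in the tissue
parameters). A constraint follows from the decomposition: the inter-rater
ICC cannot be below the test-retest ICC, because both raters view the same
scan.

**Noise.** Rician: $S' = \sqrt{(S+n_1)^2 + n_2^2}$ with
$n_1, n_2 \sim N(0, (S_0/\mathrm{SNR})^2)$, SNR defined on the b = 0 signal,
default 30. The paperless quantities here — SNR and the biological
session-variance magnitudes — are stated defaults, not values inferred from
any dataset. Not simulated: eddy currents, susceptibility distortion, fat
signal, motion; passing tests therefore validate the analysis chain, not
robustness to acquisition artifacts.

## Reliability statistics

For each limb x region x metric stratum, `fit_icc_lmm()` fits by REML

$$y_{ij} = \beta_0 + \beta_{\mathrm{rating}(j)} + u_i + \varepsilon_{ij},
\qquad u_i \sim N(0, \sigma_p^2),\; \varepsilon \sim N(0, \sigma_r^2),$$

with the rating factor (rater or session) fixed and participants random,
and reports the **consistency** ICC
$\sigma_p^2 / (\sigma_p^2 + \sigma_r^2)$ — the fixed factor's systematic
offset does not enter the denominator. Absolute-agreement forms are out of
scope. On balanced two-rating data this equals the classical mean-squares
consistency ICC, which the test suite verifies to 1e-6.

Numerical choices and conventions:

* REML variance estimates are bounded at zero by construction, so the ICC
  lies in [0, 1]. Data with exactly zero residual variance (every
  participant's ratings agree after removing rating offsets) sit on a
  boundary the optimiser cannot represent; they are detected and returned
  as ICC = 1 directly.
* Confidence intervals: percentile bootstrap (2.5/97.5) over participants
  resampled with replacement, each keeping all ratings; default 1000
  resamples; failed refits are dropped and counted, with a warning recorded
  when more than 20% fail. The percentile bootstrap is known to
  under-cover at n = 10 — the calibration test asserts >= 85% coverage at a
  nominal 95% interval rather than pretending otherwise.
* SEM $= \mathrm{SD}\sqrt{1-\mathrm{ICC}}$, with SD pooled over all
  observations in the stratum (the plain "standard deviation" convention).
* Qualitative classes: poor < 0.50 <= moderate < 0.75 <= good < 0.90 <=
  excellent. The bin edges are left-closed by decision (0.90 itself is
  excellent); verbal definitions of these bins are ambiguous at the
  boundaries.
* The pooled model adds limb type (healthy / tendinopathy / BPTB) as a
  fixed effect so systematic limb-type offsets do not inflate the
  between-participant variance.
* `sample_size_icc()` uses the Walter-Eliasziw-Donner variance-ratio
  approximation; with a null ICC of 0, an alternative of 0.75, two ratings,
  two-sided alpha 0.05 and 80% power it gives n = 10. The null ICC and
  sidedness are stated defaults of this operation, i.e. an interpretation
  of the usual "good reliability with two raters" design sentence.

## The pipeline

`run_reliability_study()` chains cohort simulation, per-session tensor
fits, region derivation, metric extraction (diffusivities reported in
$10^{-3}$ mm$^2$/s, volumes in cm$^3$), and the ICC battery, producing one
table per reliability factor with 72 rows (6 regions x 6 metrics x 2
limbs), plus optional pooled and outlier-removed tables, CSV reports and a
manifest recording seeds, versions and the configuration hash. Stage
outputs are cached content-addressed under the output directory, and reruns
with an identical configuration are byte-identical. A thin command-line
front end (`inst/exec/tendondti`) exposes `init-config` and `run`.

## Problem sizes used in validation

The shipped tests run at deliberately small, fixed sizes chosen to exercise
every code path while keeping the suite quick to run: phantom grids of
roughly 20-50 voxels per side, 100-200 procedurally generated masks for the
geometry oracles, 100-500 voxels for fitting accuracy, 50 cohort replicates
per true ICC for recovery, and 150 replicates x 200 resamples for bootstrap
coverage. The end-to-end smoke study uses 4 subjects with noise-free
signals and zero rater jitter, for which every DTI-metric ICC must be
exactly 1 and region volumes must be exactly additive.

## Known limitations

* The image-mode cohort controls the test-retest ICC only approximately;
  exact calibration is the metric mode's job.
* Inter-rater variation in image mode is governed by the jitter amplitude,
  not by the requested inter-rater ICC (which the metric mode honours).
* No registration between anatomical and DTI frames beyond affine-grid
  resampling; no scanner preprocessing (eddy/distortion correction) is
  modelled or needed for synthetic data.
* The mirror-symmetry of medial/lateral labelling is exact only for slices
  with a unique longest diameter (see above).
* Bootstrap CIs at n = 10 under-cover; interpret them conservatively.
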