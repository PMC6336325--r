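---
title: "Methods: R1 parametric mapping and flow-surrogate comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: R1 parametric mapping and flow-surrogate comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petflow)
```

## Scope and rationale

`petflow` compares three voxel- and region-level surrogates of regional
brain function derived from PET: the delivery ratio R1 from kinetic
modelling of dynamic PIB, early-frame PIB ratio images (ePIB), and FDG SUVR.
Because flow and glucose metabolism are tightly coupled, R1 and ePIB are
candidate replacements for a separate FDG scan when a dynamic amyloid scan
is already acquired. The package implements the measurement pipeline, the
agreement statistics, and a ground-truth simulator; it deliberately excludes
everything upstream of a common voxel grid (MRI registration, spatial
normalization, motion correction, scanner reconstruction).

## Kinetic model

The simplified reference tissue model (SRTM) assumes one-tissue kinetics in
both target and reference tissue, a reference region devoid of specific
binding, and a common non-displaceable distribution volume. Its operational
equation,

$$C_T(t) = R_1\,C_R(t) + (k_2 - R_1 k_{2a})\,[C_R \otimes e^{-k_{2a}t}](t),
\qquad k_{2a} = \frac{k_2}{1 + BP_{ND}},$$

is linear in $(R_1,\; k_2 - R_1 k_{2a})$ once $k_{2a}$ is fixed, which the
basis-function fit exploits: precompute $B_\theta = C_R \otimes e^{-\theta t}$
for each candidate $\theta$, solve the two-coefficient least squares, keep
the residual-minimizing candidate. SRTM2 re-parameterizes with the reference
efflux constant $k_2' = k_2 / R_1$ held fixed globally, leaving a single
linear coefficient per candidate and markedly more stable voxelwise maps.
The pooled $k_2'$ is the median of the voxelwise $k_2 / R_1$ over voxels
with $BP_{ND} > 0.05$; below that threshold the reference efflux is barely
identifiable and the ratio is dominated by noise.

### Numerical choices

* **Convolution.** $C_R$ is linearly interpolated from its frame mid-times
  (anchored at $C_R(0)=0$, injection start) onto a uniform grid of at most
  1 s steps, in minutes. The exponential convolution uses the exact one-step
  recursion $y_i = e^{-\theta\Delta} y_{i-1} + \tfrac{\Delta}{2}(f_i +
  e^{-\theta\Delta} f_{i-1})$ (trapezoid increment), which is $O(N)$ per
  candidate via `stats::filter`. Model frames are trapezoid averages of the
  fine-grid curve over each frame interval, because frame durations span
  10 s to 600 s and point evaluation at mid-times biases the early frames.
* **The $R_1 C_R$ term** uses the measured reference frame values directly
  rather than the re-interpolated curve. This keeps the fit's design matrix
  free of interpolation error and makes the model exactly reproduce the
  reference TAC at $R_1 = 1$, $BP_{ND} = 0$.
* **Candidate grid.** 100 log-spaced $k_{2a}$ values on [0.006, 0.6] /min
  by default, wide enough for PIB kinetics in tissue and background. The
  scalar fitters (`fit_srtm`, `fit_srtm2`) additionally refine $\theta$ by
  golden-section search between the grid neighbours of the argmin, removing
  the ±2.3% quantization of the 100-point grid; noiseless round trips then
  recover all parameters to well under 1%. The voxelwise engine
  (`parametric_r1`) stays on the pure grid for speed — R1, the quantity the
  maps are made of, is insensitive to the residual $\theta$ quantization
  (noiseless voxel error < 2%, and pooled $k_2'$ within 5% of truth).
* **Constraints.** The linear solution is clipped at $R_1 \ge 0$ (refit with
  $R_1 = 0$ when violated) and a clip counter is reported; unconstrained
  background fits can otherwise go negative. Voxels whose TAC is identically
  zero are skipped (`NaN` in the maps, excluded from the fit mask). Rate
  constants are reported in 1/min; frame timing is stored in seconds and
  converted at the fit boundary.

## Static measures

ePIB images are duration-weighted frame averages over an interval, with
frames partially inside contributing pro-rata (a 20–40 s window inside 10 s
frames needs no special-casing), normalized to the reference-region mean of
the same averaged volume. SUVR divides a static image by its
reference-region mean. Both are invariant to any global dose or body-weight
scaling, so SUV scaling is metadata only. The five canonical intervals
(20–40 s, 20–60 s, 20–100 s, 20–130 s, 1–8 min) ship as named constants.

## Partial-volume correction

The geometric transfer matrix method models each regional mean as a mixture
of true regional values through the scanner/analysis point-spread function:
$W_{ij}$ is the mean over region $i$ of the PSF-smoothed indicator of region
$j$, and observed = $W$ · true is solved for the true means. The PSF is an
isotropic Gaussian whose width defaults to the analysis smoothing; the
correction is applied at the regional-mean level only. Solves refuse
condition numbers above 1e8.

Smoothing everywhere in the package uses a separable kernel of
voxel-integrated Gaussian taps (erf differences) with zero-padding at the
volume boundary. Integrated taps preserve total activity exactly and make
smoothed region indicators — hence GTM entries — available in closed form for
verification; zero padding matches the near-zero PET background and keeps
edge behaviour exactly reproducible.

## Statistics

* **Regressions** pool subject-region pairs within each group (each point is
  one region of one subject), with ordinary least squares and the two-sided
  slope p-value. A per-group-mean analysis can be had by aggregating the
  regional table before fitting, but the pooled form is the package default.
* **Bland-Altman**: differences test − reference, bias ± 1.96 SD limits of
  agreement, and a trend regression of differences on the reference value to
  expose proportional bias.
* **Regional group tests**: two-sample t-tests (pooled variance by default,
  Welch optional) per region, Benjamini-Hochberg FDR across regions.
  Regions that are constant in both groups (e.g. the reference region of
  reference-normalized maps) are reported as t = 0, p = 1 rather than an
  error.
* **Voxelwise comparison**: pooled-variance t-maps thresholded at the
  two-sided `p_voxel` quantile (default 0.005, i.e. |t| > qt(0.9975, df));
  each direction forms its own excursion set and is treated as its own
  contrast. Cluster-level family-wise error is controlled by group-label
  permutation with the maximum 26-connected cluster size as the null
  statistic, per direction. All distinct group assignments are enumerated
  when feasible (252 for 5 + 5, 77 520 for 10 + 10 exceeds the default 1000
  and is sampled), the observed labelling is always included, and a seed is
  mandatory whenever assignments are sampled. Permutation inference is used
  instead of random-field theory because it is assumption-light and exactly
  testable; with 5 + 5 subjects and a 0.005 threshold on a 16³ grid the
  cluster-size statistic is discrete, so the attainable test size is
  slightly below the nominal 0.05 (measured ≈ 0.025 over 2000 null
  simulations).

## The synthetic cohort

The generator replaces clinical scans with phantoms whose truth is known:

* **Atlas**: a deterministic spherical parcellation (default 32³ at 4 mm)
  with cerebellar grey matter (reference) and brainstem in a posterior
  slab, putamen / caudate / thalamus in the core, a white-matter shell, and
  angular cortical sectors.
* **Reference kinetics**: a Feng-style tri-exponential plasma input feeding
  a one-tissue reference region ($K_1$ = 0.35 /min, $k_2'$ = 0.13 /min).
  The curve is noiseless and deterministic; tests verify it against an
  independent ODE solver.
* **Subjects**: every voxel's PIB TAC is an SRTM forward curve with the
  region's true $R_1$ and $BP_{ND}$ and $k_2 = R_1 k_2'$; Gaussian noise is
  added with SD proportional to $\sqrt{\text{activity}/\text{frame
  duration}}$, scaled so the default coefficient of variation at the TAC
  peak is 5% — the standard reconstructed-PET approximation (noise is not
  Poisson and no scanner physics is simulated). FDG uptake is linearly
  coupled to true R1 (slope 1.4, offset −0.3 in reference units) with
  per-region metabolic jitter (SD 0.03) and voxel noise (SD 0.02).
* **Groups**: PIB+ subjects draw elevated cortical $BP_{ND}$ (mean 1.5) and
  a 5% cortical R1 reduction; PIB− cortical $BP_{ND}$ defaults to 0.10 —
  near zero, but deliberately not zero, since the $k_2'$ pooling rule needs
  a non-empty $BP_{ND} > 0.05$ population in every subject, and white
  matter keeps a nonspecific 0.4 in both groups, as real PIB scans do.
  Between-subject variability is lognormal jitter on regional R1 (sdlog
  0.05) and $BP_{ND}$ (sdlog 0.25). Cortical R1 means sit in [0.8, 1.0]
  with putamen high (1.13) and caudate low (0.70), mirroring the regional
  ordering reported for clinical data.

What passing tests on this cohort demonstrate is internal consistency —
the pipeline recovers the truths its own forward model generated, and the
statistics are calibrated under the generator's noise. The phantom has no
realistic anatomy, no motion or registration error, Gaussian rather than
reconstruction-correlated noise, and flow-metabolism coupling that is linear
by construction, so agreement statistics on synthetic data (correlations
≈ 0.98) are upper bounds, not predictions, for clinical values.

## Pipeline defaults and problem sizes

`run_pipeline()` surfaces every threshold in one config: 6 mm FWHM
smoothing (applied before TAC extraction by default; configurable, since
acquisition smoothing order is a free choice), $BP_{ND}$ threshold 0.05,
voxel p 0.005, cluster α 0.05, FDR q 0.05, GTM PSF 6 mm, 500 permutations.
The shipped problem sizes — 32³ grids, 15 + 15 subjects, 500 permutations,
500 null simulations in the acceptance script — were chosen so a full run
completes in minutes on a single desktop core while leaving every statistic
well-resolved; all are configurable upward.

## Known limitations

* Unweighted least squares throughout (no frame-variance weighting); a
  documented simplification.
* No plasma-input models; SRTM-family only, so violations of the one-tissue
  assumption in target tissue bias $BP_{ND}$ slightly (R1 is robust).
* GTM correction is regional, not voxelwise, and assumes the PSF width is
  known.
* The permutation test assumes exchangeability of subjects across groups
  under the null; covariate adjustment is out of scope.
* Registration, motion and atlas errors are out of scope: all of a
  subject's images are assumed to share one voxel grid.
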