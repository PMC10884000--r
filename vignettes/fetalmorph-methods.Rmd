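---
title: "Landmark-free fetal face morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-free fetal face morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fetalmorph)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the design
decisions taken where the design was genuinely open, and the limits of
what the synthetic validation shows. No empirical claim is made here that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis problem

Populations of fetal face surfaces (open triangle meshes in millimetres,
segmented from 3-D ultrasound between roughly 24 and 34 weeks of
gestation) differ overwhelmingly in *size*, because the fetus is growing.
The pipeline therefore factors the analysis into: (i) rigid alignment,
(ii) an explicit scalar growth model used to normalise size to a common
reference age, and (iii) a deformation model for everything that remains.
Normalising with a *growth curve* rather than per-subject similarity
registration is deliberate: inter-subject size differences at a given age
(e.g. growth restriction) are clinically meaningful and must survive the
normalisation; only the age-expected size trend is removed.

## 2. Mesh processing

Meshes are loaded from PLY/OBJ/legacy-VTK/STL, with duplicate vertices
merged at 1e-9 mm and zero-area triangles dropped at construction, so a
valid `surface_mesh` never carries degenerate cells. The canonical frame
is fixed by four landmarks (both eyes, nose tip, lip midpoint): y-up,
face looking towards +z. Landmark alignment is the closed-form rigid
(no-scaling) Procrustes fit; a point-to-point ICP with brute-force
nearest neighbours (accept-only-improving steps, hence a non-increasing
error) refines the pose. Face cropping removes triangles behind a
configurable plane or facing away from it (the crop plane of the original
workflow is not specified numerically anywhere we could anchor it, so the
default is derived from the landmarks: a forward-facing plane pushed
behind the eye line by 0.8 inter-eye distances, with a 135 degree normal
gate). Isotropic remeshing is an edge-based split/collapse/flip loop with
tangential smoothing, targeting a user-set edge length; interior vertices
move only tangentially and boundary vertices only along the boundary
polyline, which is what bounds the Hausdorff drift the tests check.

## 3. Growth model

Size is measured as `2 sqrt(pi) (lambda1 lambda2)^(1/4)` from the two
leading eigenvalues of the vertex covariance (divisor `n - 1`). The
constant `2 sqrt(pi)` makes the number interpretable (the square root of
the area of the 2-SD ellipse); it cancels in every rescaling factor, and
a test asserts that invariance. Quantile curves at tau = 0.05, 0.5, 0.95
are quadratic polynomials in gestational age (weeks; days would only
rescale the coefficients) fitted by pinball-loss minimisation. Since no
linear-programming quantile solver is part of the package's dependency
set, the fit uses iteratively reweighted least squares with a vanishing
smoothing epsilon, whose fixed point is the pinball minimiser; the
noiseless-recovery and residual-balance tests pin this down. Quantile
crossing, which quadratic fits can produce in finite samples, is repaired
at prediction time by sorting the three predicted values; raw
coefficients are preserved. Rescaling is isotropic about the vertex
centroid by `median(29)/median(ga)`, and the factor-of-one case returns
the mesh bit-identically.

## 4. Deformation model

The kernel is `K(x, y) = exp(-||x - y||^2 / lambda_V^2)` — no factor 2 in
the denominator; that convention is stated once and used everywhere
(deformation kernel, varifold kernel, mode fields of the generator).
Momenta on control points induce the field `m(x) = sum_i K(x, c_i) a_i`.

* `lambda_V = 7` mm (deformation stiffness) and `lambda_W = 7` mm
  (varifold resolution) are the defaults; they are the values at which
  the original study's model-selection settled, and the synthetic
  generator emits deformations of exactly this smoothness class.
* `n_time_steps = 1` by default: a single-displacement-step ("linear
  spline") model. All downstream statistics consume time-0 momenta only,
  so their structure is identical under full shooting; geodesic shooting
  (forward Euler on the point-kernel Hamiltonian system) is available by
  configuration for fidelity studies. The momentum equation implemented
  is `-dH/dc`, which numerically conserves the Hamiltonian to first
  order in the step — the convergence test halves the drift as the step
  count doubles.
* The data term is a *varifold* metric (squared normal dot product)
  rather than currents: segmentation pipelines do not guarantee
  consistent winding, and varifolds are invariant to it (tested).
  Registration minimises `D/noise_std^2 + a' K_V a` by gradient descent
  with backtracking; gradients are analytic for the single-step model
  (kernel chain rule through cell centers, areas and raw normals) and
  finite-difference otherwise. `noise_std` (default 1 mm) is the only
  data-versus-prior dial; the limit tests (`noise_std -> infinity` gives
  `a -> 0`) document its meaning.

## 5. Atlas estimation

Control points start on a regular grid with one-spacing padding around
the union bounding box (`floor((hi-lo)/s) + 3` points per axis). The
template initialisation automates the original manual step
reproducibly: take the subject closest to the median size, smooth
(10 sweeps of lambda = 0.5 uniform Laplacian, boundary fixed), remesh
isotropically. Estimation alternates per-subject registration
(warm-started) with template vertex updates on the summed data terms;
both stages accept only energy decreases, so the total energy trace is
non-increasing — asserted on every synthetic run. Control points whose
across-subject momenta variance (summed over x, y, z; the per-coordinate
alternative was rejected as noisier) falls below 1e-4 of the maximum are
filtered out; tests verify the dropped points are geometrically inert
(reconstruction error changes below 1%). Model selection across
`lambda_W` uses `AIC = 2k - 2 ln L` with `k = 3 n_cp` after filtering
and a Gaussian likelihood on vertex point-to-surface residuals with the
ML variance — the likelihood construction is a declared convention, as
the source analysis does not specify one.

## 6. Momenta statistics

PCA is the column-centred SVD of the `n x D` momenta matrix
(`D = 3 n_cp`). Pointwise group comparison uses Hotelling's t² on the
3-D momenta per control point with the pooled covariance
(divisor `n1 + n2 - 2`); covariances with condition number above 1e8 (or
not positive definite) receive a ridge of `1e-8 tr(S)/3` — small-sample
3x3 covariances can be singular, and the same policy is shared by the
scoring module so observed and permuted statistics are computed
identically. Continuous or joint effects use the multivariate Gaussian
likelihood-ratio statistic `n ln(det S0 / det S1)`, which the tests show
is a monotone transform of t² for a single binary covariate. Global
inference is by max-statistic permutation: labels (or the tested
covariate column) are permuted with a seeded generator, and
`p = (1 + #{max_perm >= max_obs}) / (n_perm + 1)` — the add-one
correction guarantees validity. Label permutation (not residual
permutation) is used for regression tests; with covariates that are
strongly confounded with the tested variable this is approximate, a
documented limitation. Each point also gets its own permutation
exceedance probability, which is what a "z-value map" on the template
displays at the conventional 0.5/0.1/0.05 levels. The age model is
per-coordinate OLS on gestational age with a multivariate LRT for
inference (full multivariate ML would coincide here because the design
is shared across coordinates).

## 7. Shape scores

Scores are evaluated at template *cell centers* (not vertices), where a
well-defined per-cell normal exists. From control subjects only, the
model stores the mean momentum field, its 3x3 covariance (divisor
`N - 1`) and the SD of the normal projection. The deformation score is
the Mahalanobis quadratic form (chi-squared with 3 df under a Gaussian
null; 95th percentile 7.81, reference interval [0, 7.8] at one decimal);
the orthogonal score is the signed standardised normal projection
(standard normal; 95% interval [-2, 2]). The identity
`sigma_n^2 = n' Sigma n` makes `z_o^2 <= z_d` a theorem, which is
asserted wherever both scores are computed. Cells that stay singular
even after the ridge are flagged missing rather than zeroed. No global
"atypical subject" cutoff is defined: the per-cell reference
distributions are the deliverable, and aggregating them would require a
decision rule the underlying analysis never states.

## 8. Monogenic phase asymmetry

The volume is band-passed with a single-scale isotropic log-Gabor filter
(`sigma_r = 0.55`, centre wavelength configurable; a multi-scale bank was
not adopted because the source analysis mentions none) and split into the
even part `f_e` and the Riesz (odd) parts `f_o`, with
`A = sqrt(f_e^2 + |f_o|^2)` exactly by construction. The asymmetry map is
`R = max(0, |f_o| - |f_e| - T Abar) / (A + eps)`. The threshold `T` is
specified as a 0-1 quantity, which is dimensionally inconsistent with raw
band-pass responses; it is therefore scaled by the volume-median
amplitude `Abar`, keeping `T` meaningful and making `R` exactly invariant
to global intensity scaling (tested), with `eps = 1e-3 Abar`. R is zero
on even-symmetric (ridge-like) structure and peaks on step edges.

## 9. The synthetic generator and what it does (not) show

`synthetic_population_spec()` defines the study conditions: 135 subjects
with 18 FGR-like cases, ages uniform on [24, 34] weeks, size curve
`g(ga) = 80 (1 + 0.04 (ga-29) - 0.0006 (ga-29)^2)` mm (about 45% size
gain across the window, matching the order of published fetal growth),
two orthonormal momenta modes with 3 mm and 1 mm SDs (a 9:1 variance
split), a linear age effect of 0.2 mm/week in momenta space, an FGR size
factor of 0.9 with a 1 mm outward momenta offset localised at the nose,
5% log-normal size noise and 0.3 mm vertex noise along normals (the
order of the reconstruction error reported for the clinical cohort).
Mode, age and group fields are white noise on a near-surface control grid
smoothed by the `lambda_V` kernel and Gram-Schmidt orthonormalised — i.e.
exactly the smoothness class the deformation model assumes — and effects
are injected in momenta space so recovery tests have a truth expressed in
the model's own parameters. One master seed drives everything through
counter-indexed sub-streams, so populations are reproducible subject by
subject.

What passing tests show: the estimators recover the generating growth
curve, mode structure, age direction and group effect under the model's
own assumptions, at realistic noise. What they do not show: robustness to
segmentation artefacts, missing mesh regions, landmark placement error,
or deformations outside the Gaussian-kernel smoothness class — real
ultrasound data contain all four. The cohort-level numbers of the
motivating study (reconstruction error, variance splits, clinical
p-values) depend on its data and are not reproduced here; the package
reproduces each *analysis* on data whose truth is known.

## 10. Numerical choices and problem sizes

Registration and atlas tests run at deliberately coarse settings
(template grids of 10-20 vertices per side, 5-12 subjects, 15-60 gradient
iterations) chosen so the whole suite completes in minutes while still
exercising every code path; the calibration checks use 10^6 score draws
and 400 permutation datasets of 40 subjects by 60 control points, sizes
at which the Monte-Carlo error is far below the asserted tolerances.
Ties and degenerate inputs are handled explicitly: empty cut results,
all-dropped control points, constant permutation labels and zero-variance
NCC inputs raise errors; fully degenerate covariances yield a zero t²
(no signal) rather than NaN.

## Known limitations

* Pure-R registration is desk-scale: hundreds of cells and control
  points, not the thousands of a GPU LDDMM implementation.
* The single-step deformation model is first-order; large deformations
  lose the exact diffeomorphic guarantee (shooting is available but
  slower).
* Permutation tests permute labels, not residuals, for regression
  designs with nuisance covariates.
* The monogenic module is single-scale and its threshold normalisation
  is a declared convention (Section 8).
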