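---
title: "Methods: virtual healthy twins and non-linear knee wear decomposition"
author: "kneewear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual healthy twins and non-linear knee wear decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the assumptions behind the synthetic data
generator, the numerical choices, and what the passing test suite does and
does not demonstrate about real clinical data.

## 1. The scientific problem

In end-stage knee osteoarthritis (OA) the joint space — the radiographic gap
between the femoral condyles and the tibial plateau — narrows where
cartilage has eroded. The *spatial pattern* of that narrowing (medial,
lateral, bicompartmental, antero- vs postero-medial, tibial-spine
impingement) carries information about the mechanical cause: varus limbs
load the medial compartment, valgus limbs the lateral one, a steep tibial
slope shifts the contact posteriorly. Two questions drive the pipeline:

1. Can the *pre-disease* (native) limb geometry of an arthritic patient be
   reconstructed from their deformed bones — a "virtual healthy twin"?
2. Do non-linear wear patterns, extracted without supervision from
   joint-space images, correlate with that native geometry, so that
   morphology can be read as an OA risk factor?

Real cohorts of this kind are proprietary CT databases. The package
therefore ships a first-class synthetic cohort generator whose every latent
quantity (native alignment, applied deformities, wear-pattern loadings) is
known and recorded, so the full chain can be scored against ground truth.

## 2. Synthetic limbs

`generate_limb()` builds femur and tibia as pole-capped
parametric grid surfaces (≈240 vertices per bone by default, shared
topology, hence dense correspondence across all limbs for free). Landmarks
(hip, knee, ankle centres and a medial reference) are fixed linear
combinations of template vertices, so they exist for any shape in model
space, including reconstructions.

Key modelling decisions:

* **Alignment is intrinsic.** The HKA deviation from 180° is imposed as a
  metaphyseal *bend* of each bone (half per bone), i.e. joint-line
  obliquity, not as a rigid rotation between bones. A rigid rotation would
  be unrecoverable after per-bone Procrustes alignment; a bend is genuine
  shape. This mirrors the clinical notion that constitutional varus lives
  in the bone. The bend angle is solved (by root finding) so the measured
  landmark HKA equals the requested value within 0.1°.
* **Disease misalignment is extrinsic.** `impose_arthritis()` rotates the
  tibia rigidly about the knee centre (`extra_varus_deg`), which the twin
  pipeline is expected to remove. It also translates the tibia along the
  mechanical axis (`narrowing_mm`, rejected if it exceeds the remaining
  gap) and displaces vertices outward along their normals (`outlier_map`,
  osteophyte-like). Every displacement and transform is recorded exactly;
  `revert_arthritis()` restores the input to machine precision.
* **Osteophytes are marginal.** Random smooth bumps are seeded on the rings
  *around* the articular cap, not inside it — anatomically where marginal
  osteophytes form. Central articular change is modelled separately as a
  wear-pattern collapse towards the tibia.
* **The articular surfaces are flattened caps.** The distal femoral cap and
  the (widened) tibial plateau directly oppose each other across a 6 mm
  default gap, so a narrowing translation reduces the mean joint space
  width essentially one-to-one — a property the tests exploit as an oracle.
* **Individual variation** beyond the six limb parameters is a smooth
  random normal-offset field (default 0.3 mm amplitude), seeded per limb.
  All randomness flows through explicit seed arguments; nothing touches the
  global RNG state.

The cohort roster (`generate_roster()`, `apply_exclusions()`) reproduces a
933-case retrospective database with per-sex exclusion tallies
(hip/knee arthroplasty, osteosynthesis material, segmentation errors;
798 cases retained). Exclusion reasons are generated mutually exclusive per
record so the per-reason tallies sum exactly; whether reasons overlapped in
the real patients is not recorded anywhere, so the disjoint convention is
the one that reproduces the printed margins.

## 3. Shape model and virtual twin

`build_ssm()` performs generalized Procrustes alignment (translation +
rotation only — no scaling, so millimetres stay interpretable and size is a
legitimate mode) followed by SVD of the centred coordinate matrix.
Per-bone models are built in the *same whole-limb GPA frame* as the
articulated model (aligned stacks are subset row-wise), which makes the
per-bone mode spans exactly consistent with the articulated blocks.

`robust_fit()` interleaves, until the relative coefficient change drops
below `tol` (default 1e-4, max 50 iterations):

1. nearest-neighbour correspondence from the posed model instance to the
   target vertices;
2. one-sided outlier flagging: residual > mean + `outlier_sd`·SD (default
   2). One-sided because only *protruding* deformities are disease
   artefacts; an absolute floor of 1e-6 mm prevents flagging on degenerate
   all-equal residual sets;
3. a joint Gauss–Newton step over mode coefficients and a linearized rigid
   increment on the inlier set.

Three numerical safeguards matter here, all visible in the code:

* a **rigid-only ICP warm start** brings the pose near its basin before
  shape and pose are optimized jointly (otherwise rotated targets can fall
  into spurious rotated minima);
* a **minimal-rotation penalty** (weak, residual-dominated) resolves the
  near-degenerate direction in which shape modes can mimic a small rigid
  rotation of a single bone. The penalty selects the least-rotated pose —
  exactly the convention under which training coefficients are defined —
  while genuinely rigid disease misalignment (several degrees) is
  residual-driven and recovered in the pose, not the coefficients;
* a **trust region + backtracking line search** caps the per-iteration
  rotation step and never accepts an objective increase, which also makes
  the recorded inlier-RMS history non-increasing on clean targets.

`reconstruct_twin()` reassembles the two healthy bone reconstructions into
the articulated configuration that matches them best in least squares,
solving articulated coefficients plus one free rigid transform per bone by
the same Gauss–Newton scheme. At the articulated level the modes are nearly
orthogonal to global rotations (a consequence of whole-limb GPA), so the
decomposition is well identified and the relative bone pose comes from the
healthy model. In the zero-deformity limit the pipeline reproduces
model-consistent limbs to ~0.01 mm RMS and ~0.01° coronal error; imposed
rigid misalignment of ±5° is removed to well under 0.5°.

The synthetic validation harness (`run_synthetic_validation()`) draws its
healthy cases *from the articulated model* (truncated coefficient
sampling). This is deliberate: the identity-limit criterion (zero deformity
→ sub-0.1 mm reconstruction) is only meaningful for targets the healthy
model can represent, matching the premise that validation cases are healthy
limbs consistent with the healthy population model.

## 4. Joint-space maps and images

`compute_jsw()` takes, for each femoral articular ROI vertex, the minimal
Euclidean distance to the tibial surface (closest point on any triangle,
not nearest vertex). `normalize_invert()` maps widths to wear values
against a fixed cohort-level reference (`reference_mm = 8`), so 1 means
bone-on-bone and values are comparable across cases — a per-case
normalization would destroy exactly the cross-case severity differences the
downstream analysis needs.

`conformal_flatten()` is a discrete harmonic map with cotangent weights:
the single boundary loop is pinned to the unit-square perimeter by arc
length, with corners chosen deterministically (farthest boundary vertex
from the boundary centroid, ties broken by smallest vertex id so the choice
is rigid-motion invariant, then the quarter arc-length points). On planar
square patches the map is the identity to numerical precision (linear
fields are in the kernel of the cotangent Laplacian); per-triangle
quasi-conformal distortion and flip counts are reported so tests can assert
injectivity on the deployed geometries. The chart is oriented
anatomically — `u` medial→lateral, `v` anterior→posterior — which makes
mirror augmentation an exact pixel flip.

`rasterize()` uses a thin-plate regression spline (mgcv) on the scattered
(u, v, value) samples, evaluated at pixel centres and clipped to [0, 1].
Constants and linear ramps are reproduced exactly (they span the spline's
null space); smooth fields round-trip within 0.02. The default image side
is 128; the experiment harnesses use 32 px, which is ample for the smooth
synthetic wear fields (the articular ROI contributes ~30 sample points per
case at the default mesh resolution).

## 5. The principal polynomial autoencoder

`train_ppae()` is a deliberately plain fully connected autoencoder — two
encoding layers (default 512 tanh units, then a linear map to a 15-d
latent), mirrored decoder — trained full-batch with Adam on the
masked-pixel MSE plus L2 weight decay and an optional sparsity penalty (KL
divergence between a target rate and the mean hidden activation, the
classic sparse-autoencoder form). Training is bit-reproducible from its
seed. Convolutional architectures are out of scope by design.

`fit_polynomial_bottleneck()` replaces the bottleneck after training:

1. SVD of the centred latent activations → ordered orthogonal directions
   (numerically zero singular values are dropped with a warning);
2. sequentially, each further component's scores are residualized by a
   polynomial regression (default degree 2, configurable 1–3; per-predictor
   powers, no interactions) on all *previous final scores*.

Because each residual is orthogonal to a regressor set that contains all
earlier final scores linearly, the final scores are *exactly* pairwise
decorrelated — not approximately. At degree 1 the stage reduces to plain
SVD scores, which is the lever for the PCA-equivalence property: with
linear activations the whole machine reproduces PCA of the images (tested
via principal angles < 5°). Components are ordered by residual variance;
variance fractions are taken over total latent variance, which is where the
"top-k components account for X% of latent variance" statements live. The
score-to-latent inversion is exact (the residualization is triangular), so
`component_wear_interpretation()` can decode ±k SD excursions of a single
component for qualitative labelling.

The bottleneck is fitted post hoc on the trained encoder's activations —
the reading most consistent with "replace the last layer"; joint end-to-end
training is a possible extension, not implemented.

## 6. Downstream statistics

* `cca()` — whitened cross-covariance SVD with ridge regularization
  λ = 1e-6 · trace(C) per block; permutation p-values use the
  (1 + #{r\* ≥ r}) / (B + 1) estimator under row permutation of the second
  block. With `ridge = 0` the classical identities hold exactly
  (self-correlation 1, invariance under invertible within-block
  transforms); the tests pin both.
* `lda_risk()` — strict leave-one-out CV around MASS's LDA; all rates are
  computed from held-out predictions only. The discriminant score is
  sign-stabilized per fold (positive class scores higher on the training
  fold) and its Pearson correlation with the binary label is the reported
  pointwise r. "k-fold leave-one-out" is contradictory as a phrase; strict
  LOO (k = n) is implemented with `k_folds` as an explicit override.
* `mahalanobis_normalize()` — loadings divided by per-mode model SDs, so
  dominant but irrelevant variance (size) no longer dominates distances.
* `embed_2d()` — classical metric MDS of Euclidean distances. It is
  deterministic and visualization-only; no quantitative claim in the
  package depends on its geometry beyond coarse cluster preservation,
  which is what the tests check (duplicate adjacency, silhouette of
  well-separated clusters).

## 7. Experiment harnesses and their study conditions

All harnesses run from one `experiment_config()` whose defaults are the
package's study conditions: training cohorts of 40 limbs (HKA ~ N(180, 3°),
torsions N(0, 3°), slope N(3, 1.5°), bowing N(0, 1.5°), scale N(800, 15) mm,
0.3 mm shape noise), osteophytes of 3 mm on 5 % of the marginal knee
region, 2 mm narrowing, ±5° misalignment, 32-px images, 15-d latent with a
64-unit hidden layer, degree-2 polynomials. Every harness derives all its
randomness from `config$seed` through one ladder and emits a config hash.

Two design points deserve explicit justification:

* **Wear–geometry study.** The medial-minus-lateral wear contrast carries a
  planted correlation with the native HKA angle. The noise component is
  orthogonalized against the alignment covariate in-sample, so the planted
  correlation is exact for the generated cohort and the recovered canonical
  correlation measures *chain fidelity* (collapse → joint-space image →
  PPAE scores → CCA) rather than the binomial noise of the draw. Disease
  misalignment is generated to track the wear contrast (varus collapse
  follows medial wear, with independent jitter), as it does clinically; an
  independent misalignment of ±5° would physically overwrite the planted
  pattern in the joint gap — the joint space responds to the actual tilt,
  whatever its origin.
* **Negative control.** The twin arm and the control arm use *disjoint*
  healthy limbs. A literal paired design (each limb serving as its own
  control) makes leave-one-out LDA collapse into its well-known
  anti-learning artefact: the held-out case's near-identical counterpart
  sits in the training set with the opposite label, producing |r| near 1
  that measures the cross-validation scheme, not the pipeline. The
  unpaired design tests the actual claim — that reconstruction introduces
  no phenotype signal — and yields median |r| ≈ 0.08–0.13 over ten seeds
  under the default conditions.

Problem sizes in the harness defaults, tests and the acceptance script
(25–40 training limbs, 6–200 cases per experiment, 16–32 px images, 64-unit
hidden layers, a few hundred epochs) are the package's desk-scale choices:
large enough that every property being asserted is stable across seeds,
small enough that the whole suite runs in minutes on one CPU.

## 8. What the tests do and do not show

The generator emulates: dense anatomical correspondence, controllable
alignment encoded in bone shape, disease artefacts that are outliers with
respect to a healthy shape model, and wear fields that are smooth mixtures
of a small number of spatial patterns. It does **not** emulate: real
condylar anatomy, segmentation noise with spatial structure, cartilage (the
synthetic joint space is bone-to-bone), osteophytes that merge smoothly
into articular remodelling, or population covariance between alignment,
torsion and slope. Consequently, green tests demonstrate that the
*algorithms* are correct and that the *chain* recovers known structure
under controlled conditions; they do not certify clinical error magnitudes.
Printed clinical figures (sub-millimetre twin RMS, ~1° coronal error,
PPV ≈ 0.8) depend on the real cohort and the real 622-limb healthy model
and are reported by the harnesses for their own synthetic conditions only.

Known limitations: the rotation/mode degeneracy of single-bone fitting is
resolved by a minimal-rotation convention (Section 3) — fitting bones whose
true pose is far from the model frame requires the rigid warm start to
land in the right basin; the harmonic flattening is conformal only in the
limit of fine meshes and mild curvature (distortion is reported, not
optimized); and LOOCV LDA inherits the usual small-sample pessimism near
the null, which is why chance-level checks are framed as binomial bands
rather than point values.
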