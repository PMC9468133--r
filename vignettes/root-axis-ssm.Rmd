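---
title: "Predicting dental root axes from crown landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dental root axes from crown landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentaxis)
```

## The task and its assumptions

Digital dental workflows routinely capture crown morphology (intraoral or
plaster-cast surface scans) but not root morphology, which requires CBCT.
Since crowns and roots of human teeth covary in shape, a statistical shape
model (SSM) trained on joint crown + root landmark configurations can
estimate root position and axis from crown landmarks alone — for fully
dentate arches and, using the neighbouring teeth, for a missing tooth.

The method rests on three assumptions worth stating explicitly:

1. **Correspondence.** Every individual is annotated with the same labeled
   landmarks. The default protocol uses 130 crown landmarks (cusp tips,
   incisal edges, central fissures; counts vary by tooth class) and 5 root
   landmarks per tooth: LM-1 in the root-canal center at the level of the
   cemento-enamel junction line (CEJL), LM-2..LM-4 at 2 mm apical steps
   along the canal, LM-5 at the root apex. Multi-rooted teeth are treated
   as one merged root. Totals: 130 + 140 = 270 landmarks per individual;
   per jaw 132 (upper) and 138 (lower).
2. **Low-rank covariation.** Shape variation across individuals is
   approximately Gaussian around a mean configuration, concentrated in a
   few modes that couple crown and root landmarks. The coupling is the
   identifiability condition: without it, crowns carry no information
   about roots and the model cannot beat the mean shape.
3. **Size is signal.** Jaw size is anatomical information, so alignment
   removes translation and rotation only. A configuration's centroid size
   is preserved exactly through model building.

The per-tooth crown landmark allocation is configurable; the default
(upper jaw 3/3/3/5/5/6/6 from central incisor to second molar per
quadrant, lower jaw 4/3/3/5/5/7/7) reflects that lower first molars carry
an extra cusp and sums to the 130-crown total. A symmetric allocation
across jaws cannot reach that total (parity), so the jaws differ.

## Tooth axis fitting

The tooth axis is fitted through LM-1..LM-4 only; LM-5 (the apex) is kept
in the data model but excluded, because the apex of curved or multi-rooted
teeth deviates from the canal direction of the coronal two thirds. The fit
is *orthogonal* (total) least squares: the line through the centroid of
the four points along their dominant principal direction, which minimizes
the sum of squared orthogonal distances. An ordinary regression of two
coordinates on the third would make the axis depend on an arbitrary
coordinate choice; the orthogonal fit is frame-independent (equivariance
under rigid motion is asserted in the test suite), at the cost of possibly
differing by fractions of a degree from an axis fitted coordinate-wise.
Using four landmarks averages out placement error in any single one.
Degenerate input (all four points within 1e-9 mm of one point) is an
error.

Angles between axes are computed as `atan2(|a × b|, |a · b|)`, which is
mathematically `acos(|a·b|)` but numerically exact near 0° and 90° — with
`acos`, double-precision rounding alone floors the angle at about 2e-6
degrees, which matters when asserting that identical axes differ by 0°.

Accuracy of a predicted axis against the actual one is summarized by the
undirected angle between the two fitted axes (*angle alpha*), and the
distances from the predicted LM-1 (*distance A*, cervical) and predicted
LM-4 (*distance B*, apical) to the actual axis line.

## Alignment and model building

Generalized Procrustes alignment iterates: center every configuration,
rotate each onto the running mean (Kabsch solution with reflections
forbidden), update the mean; initialization is the first individual,
convergence when the mean moves less than 1e-7 mm RMS (cap 100
iterations). Scale is never normalized. The aligned flat vectors enter a
PCA (sample covariance, divisor n−1); modes whose variance falls below
`max(λ₁·1e-12, 1e-18 mm²)` are discarded as numerical zeros, and the
smallest leading set reaching the target variance fraction (default 0.98)
is retained.

Models are **per jaw**: clinical accuracy is reported per jaw, the jaws
are rigid bodies that move relative to each other, and a joint model would
entangle occlusion with tooth shape. Fitting both jaws is two calls to
`dental_ssm()`.

## Reconstruction from a partial observation

A new case supplies a subset of landmarks (typically all crowns of a jaw,
or all crowns minus one tooth's) in its own coordinate frame. Inference
proceeds in model space:

1. **Pose.** Rigid Procrustes (no scaling) of the observed landmarks onto
   the corresponding mean-shape landmarks; at least 3 non-collinear
   landmarks are required.
2. **Scores.** Posterior mean of the mode scores under the
   probabilistic-PCA observation model with isotropic landmark error σ
   (default `noise_sd_mm = 0.3`, the order of scan plus landmarking
   error):
   `s* = (Σ⁻¹ + MᵒᵀMᵒ/σ²)⁻¹ Mᵒᵀ(x_obs − µᵒ)/σ²`.
   As σ → 0 this tends to unregularized projection (available as
   `method = "projection"`); larger σ shrinks toward the mean. The
   posterior default degrades gracefully when the observation is noisy or
   the observed block ill-conditioned.
3. **Pose refinement.** The initial pose targets the *mean* crowns, which
   biases the rotation for shapes far from the mean. Pose and scores are
   therefore refined alternately — re-posing the observation onto the
   current reconstruction — until the pose is stationary (1e-12, cap 20
   iterations). This deterministic coordinate descent reproduces
   noiseless in-model observations exactly, a property the tests assert.
4. **Plausibility clamp.** The score vector may be shrunk so its
   Mahalanobis norm does not exceed `max_mahalanobis` (default `3√m`),
   keeping reconstructions inside the plausible shape region; `Inf`
   disables it.
5. The full configuration `µ + M s*` is mapped back to the case's frame;
   axes are fitted on the predicted LM-1..LM-4 per tooth.

`method = "mean"` fixes all scores at zero — the mean-shape baseline, the
no-information reference any useful model must beat.

## The evaluation protocol

`loocv_axes()` implements leave-one-out cross-validation: for each
individual a model is trained on all others (leakage-free by
construction, asserted by test), the held-out case's crown landmarks are
taken as given, roots are reconstructed and axis errors computed against
the case's actual root landmarks. Two scenarios exist: the full dentate
arch (all 14 crowns observed, all 14 teeth evaluated) and the
missing-tooth scenario (one tooth's crowns removed; by default only the
removed tooth is scored, since the other teeth's errors are essentially
those of the full scenario). Running all 14 single-tooth scenarios of a
jaw reuses one set of per-fold models — the training fold does not depend
on the scenario.

Summaries report mean ± sd (divisor n−1) per tooth and pooled per jaw;
single-measurement groups report sd 0 with an explicit flag rather than
NA, keeping tables total. Scenario differences are tested per tooth and
metric with two-sided paired *t*-tests across individuals, Holm-corrected
within one family per jaw (14 teeth × 3 metrics = 42 tests; the family is
a package choice, configurable by slicing the result). Degenerate
zero-variance differences report a signed infinite t with p = 0 and a
flag.

## The synthetic generator

No patient landmark data are distributable, so validation uses a
generator that emulates exactly the structure the SSM assumes. The
template is a deterministic idealized dentition: tooth centers on a
parabolic arch (60 × 45 mm), crown landmarks as cusp-like offsets around
each crown center, canal landmarks at exact 2 mm steps along a per-class
inclined axis, apex at the per-class root length (incisor 12, canine 16,
premolar 13, molar 12 mm), mirror-symmetric across the midsagittal plane.
Variation modes are parametric deformation fields — arch width, arch
depth, buccolingual inclination about the CEJL, mesiodistal tilt,
vertical size, root flare — so crowns and roots genuinely covary;
additional modes beyond six are seeded random fields. Individuals are
`template + Σ s_j · mode_j + noise`, optionally under a random rigid
pose; scores are centered normal with per-mode sds (default 4, 3, 2,
1.5, 1, 0.8 mm), every draw fixed by one seed.

Each field is orthogonalized, per jaw, against the rigid tangent space of
the template *and of every previously accepted field* (translations plus
infinitesimal rotations). This makes the fields pure shape modes: all
cross-products entering the Procrustes rotation are symmetric, so
scale-free alignment leaves in-span populations unrotated and PCA
recovers the generating subspace exactly — which is what lets the test
suite assert subspace recovery to 1e-6 rather than "approximately".

Three presets fix the study conditions: `smoke` (n = 10, 2 modes, noise
0.05 mm, seed 1011) for fast end-to-end runs, `default` (n = 30, 4 modes,
noise 0.05 mm, seed 2022) as the validation benchmark, and `paper_scale`
(n = 71, 6 modes, noise 0.15 mm, seed 3033) matching the size of a
realistic clinical cohort (71 × 270 = 19,170 landmarks). The landmark
noise (0.05–0.15 mm) reflects digitization precision, deliberately below
clinical landmark-placement error: the benchmark bounds algorithmic
error, not clinical accuracy.

### What passing tests do and do not show

The generator draws from the model family the SSM assumes — Gaussian
low-rank variation, isotropic noise, exact correspondence. Real
dentitions violate all three to some degree (non-Gaussian shape classes,
spatially correlated landmarking error, ambiguous fissure landmarks), and
real crown-root coupling is weaker than the constructed fields'. Passing
the benchmark therefore demonstrates correctness of the machinery and
identifiability under the stated assumptions; it does not certify
clinical accuracy, which must come from CBCT-validated cohorts. On the
default benchmark the LOOCV mean angle error is about 1° against a
mean-shape baseline of about 1.4°, and removing one tooth barely degrades
the prediction — the qualitative pattern expected when neighbouring
crowns share most of their information. Note that with 30 paired cases
and sub-0.1° systematic differences, a handful of the 42 Holm-corrected
scenario tests can reach significance on the benchmark precisely because
its noise floor is so low.

## Numerical choices

* Kabsch rotations forbid reflections (sign-corrected SVD).
* GPA convergence 1e-7 mm RMS; permuting the dataset changes results only
  within that tolerance (initialization is the first individual).
* PCA rank cut `max(λ₁ · 1e-12, 1e-18)`; degenerate-axis cut at dominant
  singular value 1e-9 mm; collinearity cut for pose at second singular
  value 1e-9.
* Coordinates serialize with 4 decimals (0.1 µm) in CSV; model files and
  manifests serialize at full double precision in JSON, so save/load
  round-trips are exact to machine precision.
* All stochastic steps (generation, simulation) run from one explicit
  integer seed; the analysis pipeline itself is deterministic, and the
  command-line layer writes no timestamps, so identical invocations are
  byte-identical.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run the full protocol at
moderated sizes — populations of 5–30 individuals (71 for the
cohort-scale counts), LOOCV with all 14 missing-tooth scenarios per jaw,
and five replicate seeds for the baseline-comparison property — chosen so
the whole suite completes in well under a minute of compute per file
while still exercising every code path at full landmark dimensionality.

## Known limitations

* The method predicts an *axis*, not a root surface; apical curvature
  beyond LM-4 is represented only by the excluded LM-5.
* Per-tooth crown landmark counts are a documented default, not a
  clinical standard; real protocols should be encoded via
  `default_protocol(crown_counts = ...)`.
* The paired-test family (42 per jaw) and the posterior defaults
  (σ = 0.3 mm, 98 % variance, clamp 3√m) are package choices; they are
  exposed as arguments and should be revisited for real cohorts.
* Only landmark-level input is supported: segmentation, mesh registration
  and CBCT/scan superimposition are upstream of this package.
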