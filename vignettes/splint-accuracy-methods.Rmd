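---
title: "Quantifying the accuracy of planned maxillary repositioning from fiducial screws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the accuracy of planned maxillary repositioning from fiducial screws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splintaccuracy)
```

## The measurement problem

In orthognathic surgery a Le Fort I osteotomy detaches the maxilla so it can
be repositioned according to a virtual surgical plan. The new position is
transferred to the patient through an occlusal splint seated on the mandible,
so the achieved maxillary position inherits two error sources: the surgeon's
ability to seat the mandibular condyles in their planned (centric) relation,
and the intrinsic error of the splint itself (design, fit, manufacture).

This package quantifies both, starting from the 3D coordinates of nine
fiducial bone screws — three each in the skull, maxilla and mandible —
measured at two timepoints: the *planned* configuration and the
*post-operative* result, expressed in a common frame (the skull, untouched
by surgery, serves as the registration reference upstream of this
pipeline). The coordinate frame is right-handed with x = medio-lateral
(positive toward the specimen's left), y = antero-posterior (positive
anterior), z = supero-inferior (positive superior); units are millimetres
and degrees throughout.

## Rigid pose differences

Each region's three screws form a *fiducial triad*. Its **barycenter** (the
component-wise mean of the three screws) is the region's rigid-body
reference landmark; the three barycenter-to-screw vectors encode its
orientation. Between timepoints we report, per region:

* **translation**: the barycenter displacement, post-operative minus
  planned, resolved per axis, plus its magnitude;
* **rotation**: the least-squares proper rotation $R$ aligning the planned
  vector triad onto the post-operative one, i.e. the Kabsch / orthogonal
  Procrustes solution of $\min_R \sum_i \lVert R v_i^{plan} - v_i^{post}
  \rVert^2$ with the reflection branch excluded. This is the standard exact
  estimator for corresponding landmark sets; the post-rotation RMSE over
  the three vectors is reported as a rigidity diagnostic.

Angles are extracted from $R$ as pitch (about x), roll (about y) and yaw
(about z). The default `standard` convention is the full Euler
decomposition of $R$ with composition order $R = R_x(\text{pitch})\,
R_y(\text{roll})\, R_z(\text{yaw})$; at the few degrees involved in
surgical repositioning the order is a second-order effect, but it is fixed
and documented so results are exactly reproducible. A `y_axis_literal`
convention is also provided, evaluating the single-axis arctangent
formulas sometimes used in the craniofacial literature on the transformed
+y axis alone. Those formulas cannot sense rotation about y, and their yaw
expression $\operatorname{atan2}(y_y, y_x)$ returns 90° at the identity,
so the literal convention exists for traceability with that literature,
never as the default. Two-argument `atan2` is used wherever a quotient
arctangent appears, to resolve the quadrant.

Near $|\text{roll}| = 90°$ the Euler decomposition is singular (gimbal
lock); the angles are still returned under a documented convention and a
flag is raised. Surgical rotations are an order of magnitude smaller, so
the flag effectively marks corrupt input. Degenerate (collinear) triads
are rejected at construction, with a default threshold of 1 mm² triangle
area: screws are placed centimetres apart, so a near-collinear triad is a
data-entry error rather than a real configuration.

## Accuracy statistics

For a series of signed differences $d_1 \dots d_n$ across specimens
(one axis or angle of one region):

* $\mathrm{RMSD} = \sqrt{\tfrac1n \sum d_i^2}$ — note the $1/n$ divisor,
  so a constant offset is fully reflected (signed means cancel);
* Bland–Altman limits of agreement $\bar d \pm 1.96\,s$ with the sample SD
  ($n-1$ divisor) and the 1.96 multiplier fixed (not t-based);
* 95% confidence intervals around each limit of half-width
  $t_{0.975,\nu}\sqrt{3 s^2 / n}$, where $\sqrt{3 s^2/n}$ is the standard
  error of a limit. The degrees of freedom default to $\nu = n-1$
  (conventional); $\nu = n$ is available because published tables are
  sometimes computed that way, and at $n = 10$ the two differ by under 2%.

The pairing of the $1/n$ RMSD with the $n-1$ sample SD gives the exact
identity

$$\mathrm{RMSD}^2 = \bar d^{\,2} + s^2 \frac{n-1}{n},$$

which `stats_from_limits()` exploits to recover the mean, SD and implied
RMSD from a published pair of limits. `check_consistency()` applies this
cell-by-cell to flag published RMSD/limits table pairs that cannot have
come from the same series. Classification against the clinical cutoffs —
2 mm translational, 4° rotational, both inclusive — uses the RMSD;
Bland–Altman statistics keep the signs.

Report renderings round to 2 decimals, half away from zero; CSV outputs
keep full precision.

## Error decomposition

Because the maxilla is positioned through the splint riding on the
mandible, the maxillary repositioning error decomposes as
$\mathrm{MxRE} = \mathrm{MdRE} + \mathrm{SE}$. The splint error is
computed by **per-specimen, per-component subtraction**
$\mathrm{SE} = \mathrm{MxRE} - \mathrm{MdRE}$ *before* any aggregation;
subtracting aggregate RMSDs is not equivalent (RMSDs only obey a triangle
inequality) and cannot reproduce a consistent table set. For rotations the
component subtraction is a small-angle approximation of the relative
rotation $R_{mx} R_{md}^\top$; the exact composition is available via
`relative_rotation_angles()` and agrees with the subtraction to better
than 0.1° in the 1–3° regime typical of condylar and splint errors (the
discrepancy grows quadratically with angle).

**Screw deformation** is quantified as the non-rigid remainder: after the
best-fit rigid transform between a region's two triads, the per-screw
residual vectors are resolved per axis, and their RMSD across screws and
specimens gives a per-region, per-axis deformation table — the standard
fiducial-registration-error construction. The alternative reading (change
in pairwise inter-screw distances) is scalar per pair and cannot be
resolved per axis; it remains available via `inter_point_distances()`,
whose rigid invariance makes inter-timepoint changes a complementary
deformation signal. Deformation RMSDs are also expressed as percentages of
the overall RMSD on the same axis (`ipd_fraction()`).

An optional mandible-fixed analysis frame (`study_config(frame =
"mandible")`) re-expresses all post-operative coordinates by undoing each
specimen's best-fit mandibular motion, so maxillary differences then
reflect the splint alone. With a rotational mandibular error this
conjugates the splint rotation by the mandibular rotation, so it equals
the skull-frame subtraction only to first order — which is exactly why
both views are useful diagnostics.

## The synthetic specimen generator

No raw coordinates ship with this package; `simulate_study()` generates
complete studies with known ground truth instead. It emulates the cadaver
study design this pipeline was built for:

* 10 specimens by default, each with the nine-screw template geometry
  (fixed, anatomically plausible coordinates: nasion/infraorbital rims;
  anterior nasal spine/upper first molar roots; symphysis/lower first
  molar roots — shipped constants so all tolerances are conditioned on
  reproducible geometry, with inter-screw distances above 20 mm);
* a planned maxillary movement of 5 mm advancement with asymmetric
  vertical repositioning (4 mm superior at the left pterygo-maxillary,
  3 mm superior at the left naso-maxillary, 3 mm inferior at the right
  pterygo-maxillary buttress), realised as the rigid transform
  least-squares fitted to those three prescribed point displacements —
  the plan prescribes buttress displacements, not a transform;
* a mandibular (condylar seating) error and a splint error, each drawn as
  independent axis-wise normal translations plus Euler rotations, matching
  the axis-wise normality the Bland–Altman analysis assumes;
* anisotropic per-screw deformation noise, per region and axis.

Error transforms are parameterised as a rotation **about the moving
region's own barycenter** plus a barycenter translation, and the maxilla
receives the splint-after-mandible composition in that parameterisation
(rotations multiply, barycenter translations add). This choice makes the
generative model realise the additive decomposition exactly: with zero
deformation noise the pipeline recovers each specimen's mandibular and
maxillary transforms to 1e-9 and the splint translation components
exactly. A fully kinematic alternative (the mandibular motion acting on
the maxilla as a global rigid map about the mandibular barycenter) would
make the translation decomposition exact only to first order in the
rotation angles; the tests quantify precisely that difference through the
mandible-frame mode.

The default error magnitudes are invented, fixed once, and chosen to be
surgically realistic rather than fitted to any published table: condylar
translation SDs (1.0, 0.9, 0.6) mm and rotations (1.0, 0.6, 0.9)°; splint
translation SDs (0.6, 0.8, 0.5) mm with a deliberately wide 2.0° pitch
spread (occlusal wafers constrain pitch least); deformation SDs largest on
the mandible antero-posterior axis (0.85, 1.90, 0.65) mm — the direction
loaded by maxillo-mandibular fixation wiring — versus (0.25, 0.35, 0.30)
mm for the skull and (0.40, 0.30, 0.35) mm for the maxilla. The skull
never receives a transform; its pose difference reflects deformation
noise alone, mirroring its role as registration reference.

What the generator does **not** emulate: CT acquisition and segmentation
error structure (it draws i.i.d. normal perturbations, not spatially
correlated surface-registration error), occlusal anatomy, biomechanical
screw bending (deformation noise is isotropic per axis, not a bending
model), or inter-specimen anatomical variation (one fixed template).
Passing tests therefore demonstrate the correctness of the estimators and
statistics under the stated generative model, not the field accuracy of
any surgical workflow.

## Numerical choices and verification sizes

* Rotation estimation is exact (SVD); the reflection branch is excluded by
  sign-correcting the smallest singular vector pair.
* The test suite checks the Kabsch solution against a dense grid-search
  oracle over rotation space (5° coarse pass within ±25°, refined locally
  to a final step below 0.03°) on 20 noisy instances, and checks noise-free
  rigid round trips to 1e-9.
* The statistical identities (RMSD/mean/SD, limit inversion) are asserted
  to 1e-12 on random series; limit coverage is checked on 10,000 simulated
  10-specimen replicates; generator parameter recovery pools 500 simulated
  studies and requires the empirical limits to sit within three Monte-Carlo
  standard errors of the generating $\mu \pm 1.96\sigma$. These sizes give
  Monte-Carlo error comfortably below the asserted tolerances while keeping
  the default suite fast.
* Published-table cross-checks: the limits→RMSD identity reproduces the
  corresponding published RMSD cells at 2 decimals for 20 of 21
  translational/rotational cells (the remaining cell differs by 0.006,
  within the ±0.01 propagation of the limits' own printed rounding), and
  flags the published splint rotational cells as internally inconsistent
  with their limits — the consistency check doing its job.

## A worked example

```{r example}
sim <- simulate_study(sim_config(), seed = 2026)
report <- run_analysis(sim, study_config())
report$overall_rmsd[report$overall_rmsd$region != "skull",
                    c("region", "component", "rmsd", "within_cutoff")]
```

```{r example-splint}
report$splint_rmsd[c("component", "kind", "rmsd", "within_cutoff")]
max(report$consistency$discrepancy)  # limits and RMSD tables agree exactly
```

## Limitations

* The pipeline starts from fused-frame landmark coordinates; image fusion,
  screw localisation and their error structure are upstream and out of
  scope.
* Euler angle order is fixed by convention; published angle tables
  computed under a different (unstated) order can differ at second order
  in the angles.
* Bland–Altman here is the basic two-timepoint form: no repeated-measures
  or proportional-bias extensions.
* The splint rotational decomposition by signed subtraction degrades
  quadratically with angle; beyond ~10° use `relative_rotation_angles()`.
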