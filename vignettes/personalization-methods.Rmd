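---
title: "Image-registration-based personalization of finite-element body models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-registration-based personalization of finite-element body models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphforge)
```

## The problem

Finite-element human body models (HBMs) used in crash and injury simulation
are built for a handful of reference anthropometries. Adapting such a model
to a specific subject traditionally requires landmark correspondences and a
radial-basis-function or kriging interpolation, which is labor-intensive and
numerically heavy. morphforge implements a landmark-free alternative: both
bodies are reduced to label images, a dense non-rigid registration supplies
a displacement everywhere, and the mesh simply rides along.

The pipeline is:

1. **Voxelization.** The skin and skeleton surfaces of the baseline model
   and of the subject are converted to three-label images — background 0,
   flesh 1, skeleton 2 (skeleton overrides flesh where they overlap). The
   inside test is parity of ray crossings at voxel centers, with no
   partial-volume weighting: the registration consumes binary labels, so
   fractional values would only blur the boundary it must find.
2. **Rigid alignment.** Foreground centroids (optionally principal axes)
   align the subject image to the baseline image. Deterministic by
   construction.
3. **Diffeomorphic Demons registration.** With the baseline image *fixed*
   and the subject image *moving*, the registration returns a displacement
   field `u` on the fixed grid such that fixed-space point `x` corresponds
   to moving-space point `x + u(x)`.
4. **Mesh morphing.** Every baseline node moves by the trilinearly
   interpolated displacement, `x_i = X_i + u(X_i)`; connectivity, part IDs
   and contact definitions are untouched, so the personalized deck remains
   simulation-ready.
5. **Evaluation.** The baseline image is warped through the *inverse* field
   (`img_warped(x) = img_baseline(x + u^{-1}(x))`, nearest-neighbour so
   labels are never blended) and compared against the subject image with the
   DICE overlap `2|A∩B|/(|A|+|B|)` and the 95th-percentile Hausdorff
   distance; element quality (scaled Jacobian, aspect ratio, minimum edge
   length) and contact intersections quantify mesh health.

Three pipeline variants cover practice: **Type I** is the basic pipeline;
**Type II** inserts a global affine pre-scaling of the subject image (e.g.
elongating a 160-unit-tall subject by 178/160 before registration against a
178-unit-tall baseline, the scaling being undone on the morphed nodes);
**Type III** "shields" regions by substituting the baseline's surfaces for
the subject's, so those regions voxelize identically in both images and
receive (near-)zero displacement.

## The registration in detail

Per iteration, on each level of a shrink-factor pyramid:

* **Forces.** Symmetric demon forces
  `δ = (f − m∘s) J / (|J|² + (f − m∘s)²/K)`, with `J` the mean of the fixed
  and warped-moving gradients and `K` the mean squared voxel spacing. Binary
  labels are pre-smoothed with a 0.5-voxel Gaussian so they carry gradients.
  Steps are capped at 2 voxels.
* **Fluid regularization.** The update is smoothed with a 1-voxel Gaussian.
* **Exponentiation.** The update is treated as a stationary velocity step
  and exponentiated by scaling-and-squaring (halving until the largest step
  is below half a voxel, then repeated self-composition), which keeps each
  incremental warp diffeomorphic.
* **Composition and diffusion regularization.** The exponentiated update is
  composed into the accumulated field, which is then smoothed with a
  Gaussian of standard deviation `smooth_factor` voxels. The default
  `smooth_factor = 2` is the working point for whole-body label images: it
  yields fields smooth enough to preserve element quality while still
  capturing anatomy.

Iteration stops at the level's budget (defaults `{100, 50, 25}` over shrink
factors `{4, 2, 1}`) or when the mean update drops below 0.01 voxel. The
per-level foreground DICE of the warped moving image is logged and is
non-decreasing across levels on all phantom cases.

Two properties are asserted by the test suite rather than assumed: the
determinant of the warp Jacobian stays positive at every interior voxel, and
the fixed-point field inversion `v ← −u(x + v(x))` converges with a mean
composition residual well below the tolerated 0.2 voxel.

### Numerical choices

* The force normalization `K` and the 2-voxel step cap follow the classical
  demons formulation; both only bound step sizes and do not shape the
  solution.
* Gaussian smoothing uses a truncated kernel (3σ) with replicate borders.
* The moving image on the fixed grid is produced by *re-voxelizing the
  transformed subject surfaces*, not by resampling the subject image: one
  quantization instead of two. This makes self-personalization exactly
  DICE 1 and makes Type III shielding exact — a shielded region voxelizes
  bit-identically to the fixed image and therefore generates no forces at
  all. When only an image is available for the subject,
  `resample_image()` provides the conventional nearest-neighbour path.
* Field inversion tolerance defaults to 0.01 mm with 50 sweeps; translation
  fields invert exactly, smooth fields converge linearly.
* HD95 pooling: boundary voxels of each mask form the two point sets;
  directed distances come from an exact Euclidean distance transform in
  world mm; HD95 is the maximum of the two directed 95th percentiles. This
  choice is stated because percentile pooling conventions differ between
  tools and change reported numbers.
* The "flesh" metric region is label 1 only (body minus skeleton) in each
  image independently; skeleton DICE is computed but is not a
  personalization-accuracy measure when the two skeletons differ in
  topology.
* Scaled Jacobian for hexahedra is the corner-normalized triple product
  (1 for any rectangular box, ≤ 0 for inverted corners); tetrahedra are
  volume-normalized against the regular tetrahedron with the same RMS edge.
  Degenerate elements (zero edge) are flagged, excluded from ratios and
  counted, never silently dropped.
* Contact checking counts *strictly penetrating* face pairs after
  triangulating quads; exactly touching or coplanar faces — including
  conforming interfaces that share nodes — do not count. This matches the
  FE convention where flesh and skeleton meshes share interface nodes.

## The phantom generator

Whole-body models and statistical body-shape subjects cannot ship with a
package, so every claim is validated on parametric phantoms: a
z-axisymmetric spheroid torso with a spherical head (flesh), a cylindrical
spine and a spherical skull (skeleton), tessellated watertight, with a
seeded sub-millimetre radial jitter so surfaces are not perfectly analytic.
All dimensions scale with a single `height` parameter (default 120 mm — a
desk-scale miniature, chosen so that the default 2 mm voxel grid stays
around 64³ and a full pipeline runs in seconds). Because both flesh
primitives are solids of revolution about the same axis, the union volume
has a closed form that the voxelizer is tested against (within 3% at
1.5 mm voxels).

The FE mesh is a voxel-block hexahedral mesh (default 5 mm blocks): flesh
part 1, skeleton part 2, contact pair (1, 2), shared nodes at the
interface. Every baseline element is an ideal cube — scaled Jacobian and
aspect ratio exactly 1 — so any quality change after morphing is
attributable to the morph alone.

Deformations with closed-form maps and exact or numeric inverses
(fixed-point, 1e-9 mm) emulate the study conditions: `axis_scale` a stature
difference (the Type II scenario), `belly_bulge` a high-BMI soft-tissue
change (10 mm amplitude, 25 mm Gaussian radius at the default height — a
five-voxel surface move), `bend` a postural change, and a localized head
bulge stands in for a subject whose head geometry must not be trusted (the
Type III shielding scenario). The belly-bulge-with-fixed-skeleton variant
(`apply_to = "flesh_only"`) reproduces the design argument for including
the skeleton in the labels: with it, skeleton nodes are anchored by their
own matching term; without it the bulge diffuses inward, and the test suite
asserts the with-skeleton error is strictly smaller.

**What the phantoms do not emulate:** real anatomical topology (organs,
limbs, joints), intensity images, posture differences, non-watertight scan
surfaces, and the sheer voxel counts of full-size models. Passing tests
demonstrate the machinery — voxelization, registration direction,
invertibility, morphing bookkeeping, metric definitions — not clinical
accuracy on real HBMs.

## Problem sizes and tolerances used by the tests

Unit and acceptance tests run phantoms at 2 mm voxels on grids around
40×40×70 (the sphere-expansion example at 1 mm, ~112³, with a leaner
iteration schedule), which keeps the full suite in a few minutes on one
core. Accuracy thresholds mirror the method's claims: identity
personalization is exact (DICE 1.0, zero nodal motion); known translations
and scalings are recovered to < 0.5 voxel mean interior error; the
belly-bulge personalization reaches flesh DICE ≥ 0.95, HD95 ≤ 2 voxels and
mean nodal error < 1 voxel; ≥ 90% of hexahedra keep scaled Jacobian ≥ 0.5
and aspect ratio ≤ 3 (baseline being exactly 1); no new contact
intersections appear; the Type II height error stays under 1 voxel; mean
shielded-head displacement stays under 0.5 voxel.

## Known limitations

* Registration operates on (up to three-label) images; intensity (CT/MR)
  similarity metrics, B-splines/FFD and mutual information are out of
  scope, though grayscale inputs are not rejected.
* The rigid aligner is moments-based; strongly symmetric bodies leave a
  180° principal-axis ambiguity (documented; the default uses translation
  only).
* Shielding substitutes surfaces; it does not blend across the shield
  boundary, so a large mismatch at the boundary is smoothed only by the
  registration's own regularizer.
* Contact intersections are detected, and reported with element IDs, but
  not repaired.
* The LS-DYNA dialect covers `*NODE`, `*ELEMENT_SOLID` (one-line form),
  `*ELEMENT_SHELL`, `*PART`, `*CONTACT` pair extraction; all other cards
  pass through verbatim. Legacy-VTK round trips renumber node IDs to row
  order (the format has no node IDs).

## A worked example

```{r example, eval = FALSE}
base <- make_phantom(phantom_spec(seed = 1))
subj <- deform_phantom(base, deform_belly_bulge(10, 25, c(0, 32, 0)))
res <- run_pipeline(pipeline_config(base$surfaces, base$mesh,
                                    subj$surfaces, type = "I"))
print(res)
summary(res)
plot(res)                       # baseline / subject / warped mid-slices
plot(res$quality$morphed)       # quality histograms
```
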