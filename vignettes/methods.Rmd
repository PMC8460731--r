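---
title: "Restoring the spatial map from serial histology to in vivo MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring the spatial map from serial histology to in vivo MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Histopathology is the reference standard for judging whether an ablation
therapy actually killed the tissue it targeted, but producing a slide
destroys the very geometry one wants to compare against: the specimen is
excised and fixed (smooth non-rigid deformation plus an arbitrary rigid
placement), sliced into ~3 mm blocks (independent per-block motion, loss of
3D continuity), and microtome-sectioned (independent in-plane distortion of
every slide).  `historeg` rebuilds the chain of spatial mappings in the
opposite order, using only the intermediate images a careful laboratory
workflow collects — blockface photographs during sectioning, an ex vivo MR
scan of the fixed specimen — and never anatomical correspondences between
in vivo MR and histology themselves, which would bias the biomarker
comparison the map is meant to serve.

The three restoring stages mirror the three destructive ones:

* **R1** registers every histology section to its nearest (50 µm)
  blockface image: 2D affine, then multi-scale diffeomorphic intensity
  registration of the two segmentations under the sum-of-squares energy
  `E = ∫ (I₁(φ⁻¹(x)) − I₀(x))² dx`, optimized by a greedy gradient flow
  whose velocity update is smoothed by the inverse Cauchy–Navier operator
  `L = −α∇² − α∇(∇·) + γI` (spectrally, α = γ = 1; the operator is linear,
  self-adjoint and low-pass).
* **R2** re-assembles the blocks: blockface images are stacked and aligned,
  per-block surfaces are extracted, cut faces are matched block-to-block by
  currents registration propagating outward from a centre block, and the
  joined exterior is registered to the ex vivo tissue surface.
* **R3** registers feature surfaces (vessels, tumour boundaries) segmented
  from ex vivo and in vivo MR, correcting the excision deformation.

Composing R1 → block chain → exterior chain → R3 maps any histology pixel
into in vivo MR coordinates; the inverse maps MR onto any slide.  Stacking
the mapped section labels and interpolating their signed-distance fields
along the cutting direction yields a volumetric histology label in the in
vivo frame, which is then compared against imaging biomarkers with
precision, recall, Dice, and Hausdorff distance.

## Surfaces as currents

Cut faces and tissue boundaries have no landmarks, so surface matching uses
the currents representation: a triangulated surface is the sum of
vector-valued point masses `η(p) δ_c(p)` over its faces, with `c(p)` the
face centre and `η(p)` the *area-weighted* face normal.  The squared kernel
norm

```
‖S‖²_K = Σ_p Σ_p' ⟨η(p), η(p')⟩ k(c(p), c(p'))
```

uses the Cauchy kernel `k(x, y) = 1 / (1 + ‖x−y‖²/σ²)`; the dissimilarity
between two surfaces is the squared norm of the difference of their
currents (two self terms minus twice the cross term).  Area weighting makes
the measure stable under mesh refinement — a unit normal would make the
norm depend on triangulation density — and orientation matters: two
surfaces that coincide but face opposite ways *repel*.  This is physical
for cut faces: the two sides of one cut are the same surface with opposite
outward senses, so the target face is orientation-flipped before matching
(`reconstruct_blocks` does this internally).

The kernel scale σ sets the size of the shape features that drive
matching.  Defaults: 1 mm for face-to-face matching (sub-block features),
2 mm — the order of the block thickness — for the exterior and feature
stages.  Registration meshes are decimated by vertex clustering to ~1.5 mm
cells; the currents double sums are evaluated with dense kernel matrices,
which is exact (an oracle test checks agreement with the naive double loop
at 1e-10 relative).

## Optimization choices

Three different optimizers are used, each matched to the geometry of its
problem; all of them only ever accept energy-decreasing steps, so energy
traces are non-increasing.

* **Affine surface stages** (closed or well-spread surfaces): BFGS on the
  12 affine parameters with the analytic gradient, centred on the moving
  mesh centroid and initialized by centroid translation with an identity
  linear part.  Plain gradient descent was tried first and converged too
  slowly for 15° rotations; principal-axes initialization was tried and
  rejected because near-symmetric shapes give all four sign candidates the
  same energy, so it can land in a symmetry-flipped basin, whereas identity
  initialization converges to the nearest minimum — the right behaviour
  for recovering a moderate misalignment.
* **Cut-face matching** uses a *rigid* model solved by preconditioned
  gradient descent with backtracking and a per-iteration displacement cap.
  A flat, open face leaves whole affine directions unconstrained (any map
  preserving the face plane, including collapse of the normal direction),
  and quasi-Newton steps on near-symmetric cross-sections can jump to a
  180°-rotated basin of equal energy; the bounded descent cannot leave the
  basin it starts in.  Non-rigid residual is left to the flow stage.
* **Diffeomorphic stages** use a greedy flow: the vertex-position gradient
  of the currents energy is smoothed through the Cauchy velocity kernel
  (scale `velocity_kernel_scale`) and the surface is advected by one Euler
  step, recorded as one kernel velocity field.  The accumulated RKHS norm
  of the velocity, weighted by `smoothness_weight`, is added to the
  acceptance criterion, so matching stops when further improvement costs
  more deformation than it buys.  Image flows work the same way with
  grid velocity fields and Cauchy–Navier smoothing, coarse-to-fine over an
  image pyramid (factors 4/2/1 by default; 2/1 for the small phantom
  sections).

Every flow is stored as its sequence of velocity steps.  The forward map
integrates `x ← x + dt·v_k(x)` in order; the inverse applies the steps in
reverse with negated velocities and a short fixed-point refinement.
`check_diffeomorphism()` verifies a positive Jacobian determinant at probe
grid nodes and round-trip consistency (default tolerance 0.1 of the probe
spacing); ground-truth phantom deformations are validated at construction
and estimated flows after optimization.

## Block reconstruction details

The centre block anchors the chain.  The largest exterior surface carries
the most registration information, but the two end blocks' outer caps
count as exterior and would select an end block, doubling propagation
depth; the choice is therefore restricted to interior blocks.  Face
classification combines three cues: the surface-normal cone (45°), the
known cut plane positions — a face is head/foot only if it lies within
`cut_tolerance` (0.5 mm) of its cut plane — and connectivity: only the
largest edge-connected component of the candidates is kept, because the
staircase treads of a voxel-quantized side wall also face along the axis
near the plane and would bias the match.  Without the locality term the
end caps are misclassified as cut faces and the joined exterior loses its
caps, which measurably drags the global exterior registration.

The exterior-to-ex-vivo stage uses a rigid linear part plus a deliberately
local flow (velocity kernel 1 mm): the assembled blocks already live in
ex-vivo-scale coordinates, so this stage only mops up accumulated
reconstruction drift; a full affine was observed to inflate the joined
exterior (which is ~20% smaller than the closed target because cut-edge
rounding and decimation remove rim area) and a broad velocity kernel let
the rim deficit drag interior points by more than a millimetre.

In `slice2d` mode — the classic 2D slice-correspondence assumption kept
for comparison — every solved transform is constrained so motion along the
sectioning axis is a per-block translation: rigid rotations are restricted
to the slicing axis and the z-component of every velocity field is
projected to its spatial mean.

## What the phantom simulates, and what it does not

The synthetic subject is an ellipsoidal tissue volume (~15 mm along the
sectioning axis at the default 1 mm resolution) containing an ellipsoidal
necrosis lesion, tubular "vessel" and blob "tumour" features; intensities
are piecewise-constant classes with per-modality lookup tables (in vivo
MR, ex vivo MR and blockface contrasts all differ, so no stage can succeed
by intensity identity), a smooth multiplicative bias field and Gaussian
noise.  The destructive stages apply, with stored ground truth: a smooth
random excision deformation (2 mm, 6 mm correlation length) plus a small
rigid placement (≤3°, ≤1 mm); per-block smooth deformations (0.8 mm) plus
small rigid motion; and per-section smooth 2D distortions (0.4 mm).  The
per-stage magnitudes were chosen once so that the restoring stages face
sub-millimetre to millimetre errors in the same ordering as the workflow
being emulated (section < block < excision).  Landmarks (5 per stage) are
drawn inside the tissue and used only for evaluation.

Two phantom details exist specifically because their absence made the
simulation unphysically hard in ways a real laboratory is not:

* blockface intensities are sampled with linear interpolation along depth,
  so consecutive 50 µm faces morph gradually — nearest-neighbour sampling
  produced twenty identical frames and then a discontinuous jump, which no
  sequential aligner could follow;
* blockface images include the faint rim of the paraffin block, the static
  scene element a real camera sees.  Sequential alignment of *tissue
  alone* is ill-posed: the cross-section's centroid genuinely drifts with
  depth, and a full-affine aligner absorbs that anatomy into the camera
  trajectory.  For the same reason the stack aligner uses a
  translation-only model — a camera shift is a translation — while the
  other intensity registrations keep the full affine.

Limitations worth keeping in mind when extrapolating to real data: the
phantom has no staining artifacts (tears, folds), no intensity
inhomogeneity beyond a smooth bias, sharper segmentations than a real
pipeline produces (segmentation itself is out of scope — the simulator
supplies tissue and feature masks, standing in for the semi-automatic
segmentation steps of a real workflow), and a 1 mm grid, three orders of
magnitude coarser than real blockface photography.  Passing the phantom
tests therefore demonstrates the correctness of the geometry and the
estimators, not the accuracy achievable on real material.

A known observability limit shows up in two places.  Binary segmentations
constrain only boundary-normal motion (the aperture problem): tangential
and interior components of a section distortion are unrecoverable in
principle, so the 2D warp-recovery test uses a boundary-normal warp and
boundary landmarks, and interior-landmark R1 errors include an
irreducible share of the simulated distortion.  Similarly, cut faces at
steep tissue shoulders expose slightly different outlines on the two sides
of a cut (half-voxel sampling), which bounds face-matching accuracy at the
phantom's resolution; at 1 mm data resolution this registration noise in z
is of the same order as the out-of-plane block deformation itself, so the
advantage of unrestricted 3D block motion over the z-translation-only
ablation — clear in high-resolution material — need not reproduce at desk
scale.  A section flow that cannot be made invertible after conservative
retries (occasionally the case for a sliver of tissue at a block end)
falls back to its affine-only chain, so every map the pipeline ships
satisfies the diffeomorphism contracts.

## Numerical choices

* Images carry world geometry (spacing, origin at the first voxel centre,
  direction cosines); all registration runs in world millimetres.  Voxel
  centres define positions and index (0,0,0) maps to the origin.
* Isosurfaces are extracted by marching tetrahedra (six tetrahedra per
  cube, welded vertices, outward orientation enforced against the local
  inside/outside direction), after Gaussian pre-smoothing of binary labels
  (1 voxel) which removes voxel staircase bias; thin structures are
  resampled to a 0.5 mm grid first so the smoothing cannot erode them
  (`label_surface`).
* The Cauchy–Navier inverse uses the discrete Laplacian symbol and
  central-difference divergence symbol with a closed-form rank-one
  inversion per frequency.
* Signed-distance interpolation fills the 250 µm gaps between mapped
  section labels along the cutting direction; sections further apart than
  `max_gap` (block boundaries) are never interpolated across, and a
  half-spacing margin extends the terminal sections of each block.
* Gradient-correctness checks evaluate at generic (off-lattice) points:
  the multilinear image interpolant is non-differentiable exactly on the
  voxel lattice, so finite differences straddle kinks there.
* One global seed drives every stochastic element; per-stage sub-seeds are
  derived deterministically from it, so any stage can be regenerated in
  isolation.

## Problem sizes used by the test suite

The acceptance checks run the default phantom (30×30×22 mm at 1 mm, five
3 mm blocks, 60 histology sections, ~300 blockface images) end-to-end
once, a three-block phantom for the 2D-slice ablation across five seeds,
20 rigid-recovery trials on a ~500-face ellipsoid, 50 random mesh pairs
for the currents oracle, and a 64² section for warp recovery.  These sizes
were chosen as the smallest instances that still exercise every code path
at the geometry of the emulated workflow.
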