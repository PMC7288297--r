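---
title: "Methods: automatic CT lung segmentation and surface reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic CT lung segmentation and surface reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the model behind the
staged lung segmentation, the parameters that matter and why they default
to what they do, what the synthetic phantom does and does not emulate, and
the numerical decisions taken where the design was genuinely open.

## The segmentation model

A thoracic CT in Hounsfield units is, to first order, a three-class scene:
air (≈ −1000 HU, both outside the patient and inside the lungs), lung
parenchyma (≈ −850 HU, air-dominated tissue), and everything else
(soft tissue ≈ +40 HU, bone far above). The pipeline exploits the wide
empty band between parenchyma and soft tissue: thresholding to
`[−4000, −400]` HU yields a binary air mask containing exactly three kinds
of structure — the exterior air touching the image border, the two lungs,
and thin air-like artifacts such as the stretcher pad under the patient.
Everything that follows is set arithmetic designed to keep only the lungs:

* **Erosion by a ball of radius 10 voxels** severs the thin air connections
  (trachea, partial-volume bridges, the stretcher's laminae) and deletes
  structures thinner than the kernel outright. We compute ball
  erosion/dilation through an exact squared Euclidean distance transform
  (a voxel erodes iff background lies within Euclidean distance `r`),
  which is algebraically identical to the textbook offset definition
  `A ⊖ B = {z : B_z ⊆ A}` but runs in linear time. Out-of-bounds voxels
  count as background, so foreground touching the scan border erodes
  inward — this is what later lets the border rule see the exterior air as
  a full-width component again after restoration.
* **Restoration** dilates by `erosion_radius + 1`. On a continuum the
  erode/dilate pair (an opening) is lossless wherever the surface's
  curvature radii exceed the kernel; on a discrete lattice the pair loses
  about half a voxel of boundary shell, because erosion removes at
  distance ≤ r while dilation restores at distance ≤ r from the *surviving
  centers*. The extra voxel over-restores instead, so the coarse mask ends
  slightly **larger** than the lung — deliberately, since the refinement
  stage trims it back with a threshold rather than with geometry. A
  consequence worth stating: the coarse mask is not a subset of the
  threshold mask, but it is always contained in the threshold mask dilated
  by a ball of radius 2 (the tests assert this envelope).
* **Component rules.** Connected components (26-connectivity, so diagonal
  contact counts) are dropped when smaller than 1000 voxels (noise specks;
  far below any lung) or when their bounding box spans the *entire* image
  extent in x or y (strict equality). The exterior air always spans the
  field after restoration, so the border rule removes it, along with
  anything fused to it. What remains, on every input the pipeline is
  designed for, is exactly two components: the lungs.
* **Refinement** re-thresholds the masked volume. Because the volume
  outside the coarse mask is set to −4096 HU — strictly below the lower
  threshold bound — re-thresholding is stable and recovers precisely the
  air voxels inside the coarse mask. A closing with radius 1 repairs edge
  raggedness. The radius is deliberately below any vessel caliber of
  interest: a closing at the coarse radius would silently absorb small
  vessels into the "air-only" mask.
* **Vessel split.** Vessels appear as soft-tissue-density holes inside the
  air mask. Closing the refined mask with a ball of radius 6 (the
  `region_close_radius`, which must exceed the vessel calibers) yields the
  lung-region envelope; envelope voxels outside the air mask and brighter
  than −400 HU are classified as vessels. The two lungs must be separated
  by more than twice this radius or the closing would bridge the
  mediastinum — the phantom respects this, and the parameter is exposed
  for data where it may not hold.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `threshold_range` | −4000 … −400 | HU | air band; both ends inclusive |
| `erosion_radius` | 10 | voxels | severs thin connections; kills thin artifacts |
| `restore_dilate_radius` | `erosion_radius + 1` | voxels | restores scale with digitization compensation |
| `fill_radius`, `fill_iterations` | 2, 700 | voxels, — | first-slice voting fill |
| `thin_ratio` | 0.5 | — | area-gain above which a first-slice component is stretcher |
| `min_component_voxels` | 1000 | voxels | small-group cutoff |
| `connectivity` | 26 | — | component adjacency |
| `refine_dilate/erode_radius` | 1 | voxels | edge repair below vessel caliber |
| `region_close_radius` | 6 | voxels | vessel-bridging envelope |
| `vessel_threshold` | −400 | HU | vessel brightness cut |
| `outside_value` | −4096 | HU | below the lower threshold bound |
| `histogram_bin_width` | 10 | HU | fine enough to separate the air and tissue modes |

All radii are counted in voxels in index space; anisotropic spacing is not
compensated (a radius-10 ball spans 20 mm in a 2 mm slice direction). This
matches the convention of the standard medical-imaging toolkits and keeps
the operators exactly testable; physical-space kernels would need
resampling and are out of scope.

### The voting hole fill and the stretcher

The voting fill flips a background voxel when at least half of its box
neighbourhood (radius 2 ⇒ 124 neighbours in 3D, 24 in a single slice —
axes of extent one contribute nothing) plus a majority margin of 1 are
foreground, iterating to convergence or 700 iterations. Foreground never
flips, so the operation is monotone and its fixed point well-defined. Under
this rule an isolated 1-voxel-thick contour gains *nothing* (at most 10 of
24 neighbours), while **laminated** thin structures — stacked plates with
narrow gaps, which is what a stretcher pad's shell looks like in the air
mask — gain their internal gap area, easily exceeding 50%. The first-slice
rule therefore fills the slice, and removes the original voxels of every
filled component whose area grew by more than `thin_ratio`; bulky regions
(lungs, exterior air) grow by a fraction of a percent and are untouched.
This interpretation — consolidate, then discard what was mostly gaps — is
one reconstruction of "removing fine contours"; a plain thin arc with no
lamination would survive it, which we consider acceptable because such an
arc is equally well removed by the erosion stage.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds the scene the pipeline assumes, with
voxel-exact ground truth recorded before noise:

* elliptic-cylinder torso (soft tissue, +40 HU) inside exterior air
  (−1000 HU) touching every border;
* two ellipsoidal lungs (−850 HU), semi-axes ≈ (23, 26, 25) voxels on the
  default 128×128×64 grid with (1, 1, 2) mm spacing;
* per lung, a vessel trunk (radius 1.6 voxels) through the hilum plus two
  branch stubs (radius 1.6, offset ±2.5 voxels), all at +30 HU. Vessel
  geometry is deliberately compact and hilum-proximal: the erosion kernel
  is nearly half a lung semi-axis at this grid scale, and only vessels
  whose erosion shadow remains surrounded by eroded core are recoverable
  by the opening. Clinical 512-grids have four times the relative room; a
  vessel tree of that richness cannot be represented at desk scale;
* a stretcher pad under the torso: three foam laminae (−600 HU, 2 voxels
  thick, 2-voxel gaps) inside a denser shell (+100 HU), following a wide
  arc spanning the full image width. In the default variant it appears in
  every slice and is removable by both the erosion and the border rule; in
  the `stretcher_first_slice_only` variant it is confined to slice 0 with
  capped ends, so that *only* the first-slice fill rule can remove it;
* additive Gaussian noise (σ = 20 HU), rounded to integer HU.

Class HU values are ≥ 11σ away from the threshold bound, so noise never
flips a voxel's class: the phantom is threshold-separable *exactly* in the
noiseless case and with probability ≈ 1 at the default and doubled noise.
This is what makes recovery deterministic across seeds, and it is also the
phantom's main idealization. Real CT additionally has partial-volume
boundary voxels, intensity drift, breathing artifacts, and connected airway
trees; passing the phantom suite therefore demonstrates the correctness of
the *operators and their composition*, not clinical-grade robustness. The
noise-doubling test (σ 20 → 40) probes the margin of the design, not a
clinical noise model.

Geometry margins are part of the design: tissue walls between lung and
exterior air exceed 3 voxels (so the one-voxel restoration overhang can
never reconnect them under 26-adjacency), and the inter-lung gap exceeds
twice `region_close_radius` (so the vessel closing cannot bridge the
mediastinum).

## Surface reconstruction

`extract_isosurface()` builds the voxel-boundary surface — the isosurface
at the 0.5 level of the nearest-neighbour-interpolated binary field:
quadrilateral voxel faces between foreground and background, consistently
outward-wound and triangulated. We chose this over an interpolating
marching-cubes variant for two reasons: the enclosed volume equals the
foreground voxel volume *exactly* (so volume checks are sharp down to a
single voxel), and a binary field gives marching cubes no sub-voxel
information to interpolate anyway — its only effect would be cutting
corners (a single voxel becomes an octahedron of 1/6 of its volume).
Smoothing is what turns the blocky surface into an anatomical one.

**Decimation** is iterative shortest-edge collapse to the edge midpoint,
with two guards: the link condition (the common neighbours of the edge's
endpoints must be exactly the apex vertices of its incident faces), which
makes every collapse a homeomorphism — component count and Euler
characteristic are provably preserved — and a normal-flip rejection that
keeps surviving faces from inverting, which in practice keeps the enclosed
volume within a percent at 50% reduction on smooth surfaces. If the target
cannot be reached without breaking topology the loop stops early with a
warning rather than erroring.

**Smoothing** applies the uniform Laplacian update
`P ← P + λ · mean(Qᵢ − P)` for `iterations` passes. With `λ = 1` a vertex
lands exactly on its neighbours' centroid (the hand-checkable cases in the
tests). Uniform Laplacian smoothing shrinks closed surfaces: on a sphere
of radius `R` triangulated at edge length `h`, each full pass pulls
vertices inward by ≈ `h²/(2R)`. The defaults (20 iterations, `λ = 0.1`)
were chosen from this estimate: they remove voxel staircasing (damping
factor `(1 − λ·λ_max)²⁰ ≈ 0.01` for the highest-frequency modes) while
bounding bulk shrinkage of a 12-voxel sphere to under 10%. An aggressive
`λ = 0.5` at the same iteration count would shrink a decimated
voxel-resolution sphere by 20–30% — more than the reconstruction error the
chain is allowed — which is why it is not the default; users wanting
stronger smoothing should raise the iteration count, not `λ`.

Ordering follows the reconstruction chain decimate → smooth: decimation on
the blocky surface is cheap and exact, and smoothing then operates on the
lighter mesh.

## Numerical choices and degenerate inputs

* Ball morphology uses the exact squared EDT (separable lower-envelope
  algorithm), so results are bit-identical to the brute-force offset
  definition — the tests assert identity, not approximation, against
  literal brute-force re-implementations on dozens of random volumes.
* Out-of-bounds is background for erosion, dilation and the voting count.
  The closing composite alone is computed on the background-padded grid so
  that its intermediate dilation is not clipped at the border; without
  this, closing would not be extensive for masks touching the border (the
  padded composition matches the safe-border behaviour of the standard
  toolkits).
* Component labels are assigned in scan order (x fastest, then y, then z)
  of each component's first voxel; ties cannot occur, so labeling is
  deterministic and the tests compare labels verbatim.
* Bounding boxes and all physical-coordinate formulas use 0-based voxel
  indices: the center of voxel `(i,j,k)` is `origin + (i,j,k)·spacing`;
  mesh vertices live on the corner lattice `origin + (c − ½)·spacing`.
* Degenerate inputs have defined behaviour: an empty mask labels to zero
  components, histograms of an empty mask are empty (not an error), a
  volume with nothing in the threshold range raises a typed
  `no_lung_candidate` condition carrying the stage report, and an empty
  mask refuses isosurface extraction.
* DICOM reading sorts by slice position, never filename; mixed series are
  an error; localizer (non-axial) slices and slices without rescale tags
  are skipped with warnings — guessing intent silently would corrupt the
  HU calibration. Non-uniform slice gaps warn and fall back to the median
  gap. Axis-aligned orientation flips are normalized by flipping the voxel
  array; oblique acquisitions are rejected, since the per-slice logic
  assumes axial geometry.

## Problem sizes

The test suite runs the full pipeline on the default 128×128×64 phantom
(about a second per run), operator-vs-brute-force equivalence on fifty
random volumes up to 18³, the mesh chain on a radius-12 digital ball, and
IO round-trips on 32³ phantoms; the whole suite completes in about a
minute on one CPU. These sizes were chosen as the smallest at which every
stage of the method is exercised at its default parameters — in particular
the radius-10 kernel needs lungs at least ~45 voxels across to survive the
opening, which fixes the 128-voxel grid.

## Known limitations

* The pipeline targets axial thoracic CT; it has no airway-tree removal,
  no left/right lung separation, and no nodule handling.
* Vessel recovery is limited to calibers between the refine radius and the
  region-closing radius (here ≈ 2–6 voxels), and the phantom's vessel
  stubs are far sparser than a real vascular tree.
* Radii are index-space; strongly anisotropic acquisitions change the
  physical shape of every kernel.
* Uniform Laplacian smoothing shrinks; for volume-critical applications
  export the unsmoothed mesh (its volume is exact) or reduce smoothing.
* Multiframe/enhanced DICOM, MR, and compressed transfer syntaxes are out
  of scope.
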