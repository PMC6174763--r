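---
title: "Methods: classical segmentation of tracked thyroid ultrasound sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classical segmentation of tracked thyroid ultrasound sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and data model

`thyrosweep` segments the thyroid in tracked freehand 3D ultrasound
sweeps. A sweep is an ordered list of 2D greyscale frames; each frame
carries a 4×4 homogeneous tracking matrix that maps the electromagnetic
tracker origin to the **centre of the image** (translations in mm), plus a
pixel spacing. The package-wide coordinate contract is:

* 0-based `(row, col)` pixel coordinates, fractional values allowed;
* in-plane axes +col → +x (mm), +row → +y (mm), plane normal → +z, image
  centre (the fractional pixel `((h−1)/2, (w−1)/2)`) at the in-plane
  origin;
* binary masks are the common currency of all segmenters and metrics,
  stored on disk as 8-bit PNG with values {0, 255}.

Four segmenters, an evaluation module, a sweep-to-volume reconstructor and
a synthetic phantom share this contract. Everything is deterministic under
a single integer seed.

# Preprocessing

Ultrasound B-mode frames carry strong multiplicative speckle and low
contrast. Before level-set segmentation each frame is contrast-enhanced by
global histogram equalization and then despeckled with a median filter.

* Equalization uses the plain CDF mapping `v → round(255·cdf(v))` over 256
  bins. It is monotone non-decreasing; a constant image maps to a constant
  (255). Global rather than adaptive equalization is used — the plain
  technique, with no tiles or clip limits to tune.
* The median filter uses reflected borders. The default kernel is 5 px: a
  standard speckle-suppression size that still preserves the boundary
  gradients the region forces rely on; it is configurable
  (`preprocess.median_kernel`).

Preprocessing is applied to **every** frame of a sweep (not only the
first), since the propagated initializations re-run the same per-frame
pipeline.

# Active contours without edges

The evolving contour is the zero level set of a signed distance function
φ. The **sign convention is φ < 0 inside**, documented here because both
conventions appear in the literature.

## Signed distance function

`make_sdf()` computes the exact Euclidean distance to the region boundary
— the contour running *between* opposite-label pixels, represented by the
midpoints of 4-adjacent foreground/background pixel pairs — using a
Felzenszwalb–Huttenlocher exact distance transform on a 2×-refined grid so
the boundary sits on grid nodes. This choice has three useful
consequences: flipping the mask exactly negates φ; for a half-plane |φ| is
exactly the row distance to the split line; and |∇φ| = 1 holds across the
boundary, so the eikonal property (|∇φ| ∈ [0.9, 1.1] on ≥ 99% of pixels)
survives discretization. A pixel-centre-to-pixel-centre transform instead
leaves a ±½ px jump at the interface that violates the eikonal band on the
whole boundary ring.

## Forces and update

The printed Chan–Vese energy is a pair of region integrals; gradient
descent on it yields the pointwise force actually used:

* image force `F_img(p) = (I(p) − μ_in)² − (I(p) − μ_out)²` with
  `μ_in = mean(I[φ<0])`, `μ_out = mean(I[φ≥0])`, signed so pixels closer to
  `μ_in` move inside;
* curvature force
  `(φ_x²φ_yy + φ_y²φ_xx − 2φ_xφ_yφ_xy)/((φ_x²+φ_y²)^{3/2} + 10⁻⁸)`,
  all derivatives central differences with reflected borders; the 10⁻⁸
  stabilizer handles flat regions.

The update is plain explicit Euler, `φ ← φ + Δt·φ_t` with
`φ_t = α·F_curv + F_img/max|F_img|` and `Δt = 1/(max|φ_t| + ε)` — so
`Δt·max|φ_t| < 1` holds at every iteration by construction (asserted at
run time) and the front moves at most one pixel per step. No
Dirac/Heaviside band is used: updates apply on the full grid, matching the
plain update equation rather than the narrow-banded original. φ is
re-initialized to a signed distance function every `reinit_every`
iterations. Evolution runs a fixed, user-chosen number of iterations — the
accuracy/time trade-off is explicitly the user's.

Defaults: `alpha = 0.2`, `epsilon = 1e-5`, `iterations = 300`,
`reinit_every = 50`. On a constant image the normalized image force is
taken as zero. If one region vanishes mid-evolution the contour is gone
and the current labelling is returned.

## Initialization propagation

The user draws one rectangle on the first frame. For frame *k+1* the
centroid of frame *k*'s mask is mapped to tracker space through frame
*k*'s matrix and back into frame *k+1*'s pixel grid through the inverse of
its matrix; a rectangle of the **same user-drawn half-sizes** is centred
there. This is a *world-fixed-anatomy* rule: the gland does not move in
tracker space, so an in-plane probe translation of +d mm moves the gland
by −d mm in image coordinates, and a purely out-of-plane step leaves the
pixel position unchanged. (The alternative reading — adding the image
centres' displacement to the centroid in pixel coordinates — doubles the
apparent motion for a fixed target; the wobble study below confirms the
world-fixed rule tracks the gland.) A frame whose propagated rectangle
falls fully outside the image, or whose evolution collapses, is recorded
as an empty mask and propagation restarts from the last successful frame —
the batch replacement for the interactive re-initializations a human
operator would perform.

# Graph cut

GrabCut-style iterative min-cut segmentation on single frames, seeded by
yellow-style foreground strokes and a violet-style closed background ring.

* **Trimap.** Pixels 4-connected to the frame border without crossing the
  ring are definite background; stroke pixels are definite foreground;
  everything else — ring pixels included — is unknown.
* **GMMs.** Greyscale scalar Gaussians (ultrasound is single-channel), 5
  components per class (reduced automatically for small classes),
  initialized by Orchard–Bouman binary splitting: repeatedly split the
  highest-variance cluster at its mean. Variances are floored at 10⁻³.
  Each iteration re-assigns every pixel to its most likely component (ties
  to the lower index) and refits means, variances and occupancy weights.
* **Graph.** N-links over the 8-neighbourhood with weight
  `γ/dist·exp(−β Δz²)`, γ = 50; β is `1/(2⟨Δz²⟩)` with the average taken
  over all 8-neighbour pairs — the expectation form, since a per-pair β
  would make the weight constant. T-links of unknown pixels carry the −log
  **full-mixture** likelihood under the opposite class's GMM; seeds get a
  hard link of weight `1 + 8γ`, which exceeds any pixel's total N-link
  weight, so seeds never change side. Because −log densities can be
  negative (densities above 1 at the variance floor), both terminal links
  of a pixel are shifted by a common constant — every s-t cut pays exactly
  one terminal link per pixel, so the argmin is unchanged and capacities
  stay non-negative.
* **Solver.** `igraph::max_flow` computes the exact min cut. Capacities
  are quantized to integers at 10⁻⁶ energy granularity: the cut is
  unchanged at that granularity and the push-relabel solver is orders of
  magnitude faster than with raw floating-point capacities of wide dynamic
  range.
* **Convergence.** Iterations stop when the labelling repeats, after
  `n_iters` (default 5) rounds, or when a proposed labelling would carry
  higher energy than the current one (a monotone-descent safeguard: the
  hard component re-assignment after a GMM refit is not guaranteed to
  lower the mixture-likelihood energy, so uphill proposals are rejected
  rather than accepted). The reported per-iteration energy — unknown-pixel
  data terms plus cut N-links — is therefore non-increasing.

Across a sweep, annotations are supplied every *n* slices (default 10,
matching an interaction every 10 slices / 2 mm at typical frame spacing).
Unannotated frames receive scribbles carried through tracker space by the
same world-fixed-anatomy mapping as the ACWE rectangles. When two
annotated frames bracket the target the stroke centroids are blended
linearly in frame index, the nearer frame's stroke *shapes* are used, and
they are additionally **scaled** by the linearly blended RMS radius of the
two translated sets: the gland's cross-section grows and shrinks along the
sweep, and a ring frozen at the nearer frame's size stops enclosing (or
stops constraining) the target section. How to blend bracketing
annotations is a genuinely open design point; this rule is deterministic
and keeps the ring a superset of the section throughout.

# Pixel-based classifier

Three local texture features per pixel, computed with reflected borders:

* `cv4` — coefficient of variation σ/μ over the 5-pixel set {centre +
  4-neighbours};
* `cv8` — σ/μ over the 9-pixel set {centre + 8-neighbours};
* `mean4` — the mean of the smaller (5-pixel) set.

σ is the **population** standard deviation; `C_v := 0` where μ = 0 (black
border regions). The neighbourhood sets include the centre pixel, which
makes `mean4` a standard 5-point smoother. Only these three features are
used — larger texture-feature sets buy little accuracy here at a
substantial time cost, which is also why decision trees are used rather
than an RBF network.

Training samples come from user clicks inside and outside the gland; all
pixels in a `(2r+1)²` patch around each click inherit the click's label
(default r = 5 — a single pixel per click would starve the trees). One
model is trained per dataset from all clicks across their frames. The
ensemble is 10 bagged CART trees (Gini splits, depth ≤ 8, bootstrap per
tree, seeded); the foreground probability is the arithmetic mean of the
per-tree leaf probabilities and the mask is `p ≥ 0.5`. A 3×3 morphological
closing bridges pixel gaps and only the largest 8-connected component
survives — the final segmented thyroid.

# Random-forest voxel classifier

The automatic method works on reconstructed 3D volumes. Each voxel is
described by 30 features from four families — Gaussian blur, gradients,
Laplacian, multi-resolution resampling:

* at native resolution (15): raw intensity; blurs at σ ∈ {1, 2, 4} voxels;
  per-axis gradients and gradient magnitude of the σ ∈ {1, 2} blurs
  (central differences); Laplacian of the σ ∈ {1, 2} blurs; and the local
  mean over a 15-voxel cubic window;
* the same 15 recomputed on a 2× average-pooled copy and resampled back
  (nearest neighbour).

The named families do not pin an exact roster; this instantiation is
fixed in code so experiments are reproducible. The 15-voxel window mean is
included deliberately: it is the only feature that uses the
characteristic 15-voxel neighbourhood size, and it completes the 15 + 15
count.

The forest has 12 binary trees of depth ≤ 10 (`ranger`, probability
forest), each grown on a bootstrap resample with a random subset of
⌈√30⌉ = 6 features per split. Voxel samples are class-balanced (default
20 000 per class per volume) — the gland is a small fraction of the volume
and training on every voxel is wasteful. The forest probability is the
mean of per-tree leaf probabilities (verified against a per-tree oracle to
10⁻¹²); masks are `p ≥ 0.5` with an optional largest-3D-component cleanup.
`cross_validate()` partitions *volumes* (not voxels) into folds, so no
gland contributes to both training and validation.

# Metrics, reconstruction and volume

* **Dice** `2|X∩Y|/(|X|+|Y|)`; two empty sets compare as 1 so
  background-only slices are not penalized.
* **Hausdorff** between foreground pixel/voxel centres, scaled per axis by
  the spacing. The directed form is what the formula prints; the
  **symmetric** max of both directions is reported (and the directed pair
  exposed as an attribute) since segmentations are compared without a
  preferred direction. Both 2D per-slice and 3D values are computed by
  `evaluate_sweep()`.
* **Reconstruction.** Frames are ordered along the line of image-centre
  positions. The voxel grid is world-axis-aligned and **cell-centred**
  (voxel *i* covers `[lo+(i−1)v, lo+iv]` — the ITK/MetaImage convention;
  it also avoids degenerate exact alignment of grid planes with frame
  planes). For each voxel layer between two consecutive frames the two
  frames' mask signed distance functions are sampled bilinearly at the
  voxel's in-plane position (through each frame's full affine inverse) and
  blended linearly along the sweep; a voxel is foreground where the blend
  is negative. Voxels exactly on the blended zero level set — e.g. the
  one-pixel growth ring between aligned rasterized sections — are split
  evenly by a deterministic checkerboard, which removes the systematic
  shrink a strict `< 0` rule produces. Signed-distance blending rather
  than nearest-slice copying is used because the inter-slice gap is meant
  to be *interpolated* shape, not replicated slices. Non-monotone frame
  positions trigger a warning and a reorder-by-position fallback.
* **Volume** = occupied voxels × voxel volume, in cm³ (default voxel
  0.5 mm, configurable).

# The phantom

The test bed for every pipeline: an ellipsoidal "thyroid lobe" of
echogenicity 60 inside tissue of echogenicity 150 (the gland parenchyma
darker than the surrounding interfaces), edge softened by a 2-px Gaussian,
multiplied by fully developed speckle — unit-mean Rayleigh noise blended
as `1 + s(N−1)` so `speckle_scale = 0` is exactly noiseless and the mean
level is preserved (default s = 0.3, a visibly grainy but segmentable
level). Tracking matrices are identity rotations translated by
`k·frame_step` along +z; ground-truth masks are exact ellipse
cross-sections; the analytic volume is `4/3·π·a·b·c`.

Two study geometries are used:

* the **default** emulates a clinical acquisition of a whole lobe:
  40 frames at 0.45 mm steps, 256×256 px at 0.075 mm/px (clinical linear
  probes resolve at this scale: the reference acquisitions are 760×500 px
  frames), semi-axes (7, 5.5, 8.3) mm with the lobe strictly inside the
  swept slab. Fine pixels matter for the volume-convergence study: the
  resolution floor of any mask-based reconstruction is set by pixel
  spacing, and it must sit below the voxel sizes being compared
  (1.0/0.5/0.25 mm) for the error to decrease monotonically;
* the **sweep study** geometry used by the per-method segmentation
  studies: 20 frames at 1 mm steps, 96×96 px at 0.25 mm/px, semi-axes
  (8, 6, 11) mm centred mid-sweep, imaging the *central portion* of the
  lobe so every frame — in particular frame 0, where the user initializes
  — shows a sizable cross-section, as an operator would choose.

`default_annotations()` derives deterministic stand-ins for the user
interactions from the ground truth: the frame-0 bounding box dilated 20%
as the ACWE rectangle, a centroid stroke plus a 30%-dilated rectangular
ring every *n* frames as scribbles, and 3 + 3 clicks. The `wobble_mm`
option adds random in-plane tracking translations to exercise propagation
robustness; rotations are not wobbled — the emulated linear-probe
acquisitions keep frame orientation fixed, and the propagation rules
consume only the centre displacement.

What the phantom does *not* emulate: acoustic shadowing, attenuation,
anisotropic point-spread, nodules and other pathology, out-of-plane probe
tilt, and the inter-observer variability of real ground truth. Passing
phantom studies therefore demonstrates algorithmic correctness and
reproducibility, not clinical-grade accuracy.

# Problem sizes and runtime choices

The bundled tests and the acceptance script run the studies at sizes a
laptop handles in minutes: single-frame ACWE/graph-cut checks at 128×128
px; sweep studies at 20 frames of 96×96 px with 400 ACWE iterations;
random-forest cross-validation on four phantom volumes at 0.5 mm voxels
(≈ 2·10⁵ voxels each, 5 000 samples per class per volume in the CV
study); reconstruction convergence on the default phantom at 1.0/0.5/0.25
mm voxels. All randomness passes through one integer seed, and repeated
runs are byte-identical in their mask outputs.

# Known limitations

* The ACWE region model assumes two-phase intensity homogeneity; glands
  with strong internal texture gradients need more iterations or a larger
  smoothing weight, and the fixed iteration count is a deliberate
  accuracy/time trade-off.
* Scribble interpolation assumes the gland's section changes smoothly
  between annotated frames; abrupt anatomy changes between annotations are
  not recoverable without more interaction.
* Reconstruction assumes frames are approximately parallel (linear
  sweeps); strongly fanned acquisitions would need a resampling step at
  the documented manifest adapter point.
* DICOM reading is a convenience adapter through `pydicom`; the canonical
  interchange format is the manifest directory.
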