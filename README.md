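# thyrosweep

Segmentation of the thyroid gland in **tracked freehand 3D ultrasound
sweeps**: ordered B-mode frames, each tagged with a 4×4 electromagnetic
tracker pose mapping the tracker origin to the image centre. The package is
aimed at researchers in medical image analysis who need reproducible,
scriptable baselines for thyroid segmentation, 3D reconstruction and volume
estimation — the measurements clinicians use to follow gland size over
time.

Four classical segmenters share a common mask/metric currency:

- **ACWE** — Chan–Vese active contours without edges. The contour is the
  zero level set of a signed distance function φ (φ < 0 inside), driven by
  the region force `(I − μ_in)² − (I − μ_out)²` and the curvature force
  `(φ_x²φ_yy + φ_y²φ_xx − 2φ_xφ_yφ_xy)/(φ_x² + φ_y²)^{3/2}` via the explicit
  step `φ ← φ + Δt·(α·F_curv + F_img/max|F_img|)` with the CFL-safe
  `Δt = 1/(max|φ_t| + ε)`. The user draws one rectangle on the first frame;
  each segmented frame's centroid is carried through the tracking matrices
  to initialize the next frame.
- **Graph cut** — GrabCut-style iterative min-cut segmentation seeded by
  foreground strokes and a background ring. Greyscale GMMs (Orchard–Bouman
  initialization) model the two classes; N-links carry the contrast penalty
  `γ/dist(m,n)·exp(−β(z_m − z_n)²)` with γ = 50 and
  `β = 1/(2⟨(z_m − z_n)²⟩)`; T-links carry −log likelihoods. Scribbles are
  interpolated across unannotated slices (annotation every 10 slices).
- **PBC** — a bagged decision-tree pixel classifier on three local texture
  features: the coefficient of variation `C_v = σ/μ` over the
  4-neighbourhood and 8-neighbourhood (centre included) and the mean of the
  smaller neighbourhood, trained from clicks inside/outside the gland,
  followed by largest-connected-component cleanup.
- **RFC** — an automatic random forest of 12 depth-10 trees classifying
  every voxel of a reconstructed volume from 30 image features (Gaussian
  blurs, gradients, Laplacians, a 15-voxel window mean, and the same set on
  a 2× downsampled copy); the forest probability is the mean of the
  per-tree leaf probabilities.

Evaluation uses the Dice coefficient `2|X∩Y|/(|X|+|Y|)` and the symmetric
Hausdorff distance (directed pair exposed). Mask stacks are reconstructed
to voxel grids by blending consecutive frames' signed distance functions
along the sweep, and thyroid volume is reported in cm³. A **synthetic
speckle phantom** (ellipsoidal lobe, multiplicative Rayleigh speckle, exact
ground truth, analytic volume) makes every pipeline testable end to end
without clinical data.

## Worked example

Segment a synthetic tracked sweep with ACWE and evaluate it against the
known ground truth:

```r
library(thyrosweep)

spec <- phantom_spec(semi_axes_mm = c(8, 6, 11), lobe_centre_mm = c(0, 0, 9.5),
                     n_frames = 20, frame_step_mm = 1,
                     pixel_spacing_mm = c(0.25, 0.25), frame_size = c(96, 96),
                     seed = 1)
gen <- generate_sweep(spec)
gen$sweep
#> tracked_sweep 'phantom-seed1': 20 frames of 96x96 px, spacing (0.25, 0.25) mm/px

ann <- default_annotations(spec, gen)   # stands in for the user's rectangle
masks <- segment_sweep_acwe(gen$sweep, ann$rect, acwe_config(iterations = 400))
evaluate_sweep(masks, gen$gt_masks, gen$sweep, voxel_mm = 0.5)
#> metric_report: mean slice Dice 0.9254 | 3D Dice 0.9337 | Hausdorff 1.50 mm | volume 2.070 cm^3 (gt 2.147)
```

The report says the automatic slice-to-slice propagation kept a mean
per-slice Dice of 0.93 against the exact phantom ground truth, the worst
boundary disagreement of the reconstructed 3D segmentation is 1.5 mm, and
the estimated lobe volume (2.07 cm³) is within 4% of the reconstructed
ground truth (2.15 cm³).

The same workflow is available from the shell via the bundled
`inst/cli/thyrosweep` script (`phantom`, `acwe`, `graphcut`, `pbc`,
`rfc-train`, `rfc-predict`, `rfc-cv`, `evaluate`, `reconstruct`
subcommands); every run writes a `run_manifest.json` with the resolved
configuration and seed. Real sweeps are read from a manifest directory
(`sweep.json` + PNG frames + plain-text 4×4 matrices) or, read-only, from
a DICOM series via the system `python`/`pydicom`.

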