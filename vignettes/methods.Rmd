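---
title: "Methods: slice-wise segmentation and contour-stitched volume estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slice-wise segmentation and contour-stitched volume estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Synovitis — inflammation and hypertrophy of the synovial membrane — drives
pain and progression in osteoarthritis of the first carpometacarpal (CMC1)
joint. 3D ultrasound can image the hypoechoic synovial region between the
trapezium and first-metacarpal bone surfaces, but turning a 3D sweep into a
synovial tissue volume (STV) estimate normally requires a trained rater to
outline the region slice by slice, at 10–20 minutes per volume. `synovol`
implements the automatic alternative: a 2D convolutional network segments
each transverse slice, the per-slice boundaries are stitched into a closed
3D surface, and the STV is read off as the enclosed mesh volume. Around this
core it provides the full measurement-science apparatus: overlap and
boundary-distance metrics with signed variants, area/volume percent
difference, normality-gated paired testing and Bland-Altman agreement
analysis.

# Data model and conventions

Volumes are arrays in `(z, y, x)` index order — slice, image row (depth
within a slice), image column — with spacing stored as `(dx, dy, dz)` in
mm/voxel. The default grid is the 0.114 x 0.114 x 0.333 mm voxel of the
mechanically swept linear-probe system the package targets. All indices are
1-based and all box bounds (regions of interest) are inclusive, matching R's
native indexing; physical quantities (contours, surfaces, distances,
volumes) are always in mm. Intensities are min-max normalized to [0, 1] at
load; a constant volume is clamped rather than rescaled.

Reslicing extracts native integer z-planes at evenly spaced indices spanning
the full depth (ends included, rounding half-up). Interpolation is
deliberately avoided so resliced label planes remain binary. Train/test
splitting is seeded and operates on whole volumes, never slices, so no slice
of one volume can leak across the split.

# The synthetic phantom

The clinical dataset behind the method is not publicly deposited, so the
package carries a seeded phantom generator that emulates the imaging
situation well enough to exercise every downstream stage:

* two bright curved bands (bone surrogates for trapezium and metacarpal),
  brightest structures in the image, with optional attenuation shadows cast
  below random lateral beam positions;
* a hypoechoic target between the bands — either a **crescent** hugging the
  upper band, with thickness varying smoothly across slices and tapering
  laterally (emulating synovial hypertrophy), or an **ellipsoid** of known
  analytic volume for oracle checks;
* multiplicative gamma-distributed speckle (`speckle_sd`, default 0.5
  relative standard deviation), the standard first-order surrogate for
  ultrasound speckle.

Echogenicity means are ordered target < background < bone and validated at
construction. All randomness flows from one explicit seed per call —
identical parameters give bit-identical phantoms. What the phantom does
*not* model: beam physics (no point-spread anisotropy, no scan conversion),
correlated speckle texture, anisotropic shadow geometry, or anatomy beyond
one target per volume. Tests passing on phantoms therefore demonstrate the
correctness of the pipeline's *measurement machinery* and the learnability
of a well-posed segmentation task — not clinical-grade performance.

A second rater is simulated by perturbing the label: each slice's signed
Euclidean distance transform is thresholded after adding a smooth
low-frequency Gaussian field (correlation length `jitter_cell`, default 16
voxels) plus a constant radius (dilation > 0, erosion < 0). Smoothness makes
the disagreement spatially correlated, as human disagreement is. Per
original connected component only the best-overlapping perturbed component
is kept, so topology is preserved; slices eroded to empty are flagged and
warned about. On thin, highly curved targets a zero-mean boundary jitter
still produces a small positive volume bias — the same curvature effect that
makes a ribbon gain more area when expanded than it loses when contracted;
on low-curvature targets the operator is volume-symmetric to well under 2%.

# The slice segmenters

No deep-learning framework is required: the package includes a compact
reverse-mode engine written in vectorized base R (im2col convolutions as
dense matrix products, max-pooling, nearest-neighbour upsampling, channel
concatenation, Adam). On top of it sit two architectures:

* **U-Net** — the classic encoder/decoder with skip connections; channel
  width doubles per level from `base_filters`.
* **U-Net++** — nested dense skip pathways; its encoder stages are residual
  (ResNet-style basic blocks with projection shortcuts), and deep
  supervision is off: the output is read from the final nested node.

The loss is binary cross-entropy plus soft-Dice. The clinical-scale recipe
(Adam, learning rate 1e-4, 100 epochs of 600 steps, batch 10, flips,
rotations to 20 degrees, translations and zooms to 20%) is the
`train_config()` default. For CPU-scale work `scaled_down_profile()` fixes a
depth-2, 8-filter U-Net on 64 x 64 inputs, Adam at 1e-3, 10 epochs of one
pass over the data, batch 10, full augmentation — sized so the desk-scale
study (30 training volumes x 10 slices = 300 slices, 10 held-out volumes)
trains in a few minutes on one core while reaching held-out Dice above 85%.
Augmentation draws come from the caller's RNG stream, so a seeded training
run is reproducible end to end; masks are re-binarized at 0.5 after the
bilinear warp. Inference zero-pads any slice to the next multiple of
`2^(depth-1)` and crops the probability map back, and is deterministic:
identical weights and image give an identical map.

Design choices that were genuinely open: the loss (BCE + soft-Dice, the
standard choice for class-imbalanced ultrasound masks), the probability
threshold (0.5, configurable), the batch size of 10, and final-weight
retention when no validation set is supplied (best validation-Dice weights
are kept when one is).

# Surface reconstruction and the enclosed volume

Per slice, the mask boundary is extracted as the 0.5 iso-contour with linear
interpolation between pixel centres (marching-squares style). Sub-pixel
contours were chosen over pixel-edge tracing to avoid the staircase bias
that inflates mean-surface-distance estimates. Contours are normalized
counter-clockwise; when a slice yields several components the largest by
enclosed area is kept (tie: first in scan order) and the rest are reported
in the warnings — the synovial region is treated as a single structure.

Each contour is resampled to `n_points` (default 64) points equally spaced
by arc length from the original start point; 64 points keep the polygonal
approximation of a circular cross-section within 0.13% of its area.
Correspondence between adjacent slices is the cyclic index offset minimizing
the sum of squared point distances, found exhaustively over all offsets —
the simplest twist-minimizing rule, and directly checkable against
brute force. Adjacent contours are joined as quad strips split into
triangles; the first and last contours are capped by triangle fans to their
centroids, closing the ends. The construction guarantees a watertight,
consistently oriented mesh (every directed edge once, every undirected edge
twice, Euler characteristic 2), and the STV is the absolute signed sum of
origin-tetrahedron volumes over faces (divergence theorem), which is exact
for polyhedra and rigid-motion invariant.

Interior slices with no segmentable region are bridged by stitching the two
flanking contours directly across the gap — for contours this *is* the
linear interpolation of the surface — or, with `interpolate_gaps = FALSE`,
the stack is split and the largest sub-surface reported. Leading and
trailing empty slices are dropped with a warning. Fewer than two usable
slices is an error: no volume can be defined. Centroid-fan caps assume
star-shaped (convex-ish) end cross-sections, which holds for synovial
regions; strongly non-convex end slices would need constrained
triangulation, which is out of scope. No mesh smoothing is applied — it
would bias volumes.

# Evaluation metrics

Confusion counts follow the usual definitions (true positive = overlapping
foreground, and so on). Precision, recall, accuracy and Dice are reported in
percent. 3D overlap metrics pool the per-slice confusion counts — averaging
and summing are algebraically identical for these ratios, and both are
provided to make that explicit. Percent difference uses the manual reference
as denominator: `(measured - reference)/reference x 100`, absolute and
signed.

Distance metrics are computed in physical mm, never pixels. MSD is the
symmetric mean of the two directed mean nearest-neighbour distances; HD the
larger directed maximum; nearest neighbours are exhaustive (chunked), which
is exact and fast at the point counts involved (hundreds to a few thousand).
Signed distances give each predicted boundary point the sign of its position
relative to the gold-standard interior — positive outside by default, with a
flag to flip the convention since published tables are not consistent about
it. The interior test uses the nearest-voxel lookup in the gold-standard
mask.

Degenerate cases follow a fixed convention and are flagged: two empty masks
score 100% overlap (nothing to find, nothing found); an empty prediction
against a non-empty gold standard scores 0% precision. These arise only in
testing — clinical studies excluded volumes without synovitis.

# Statistical layer

Paired comparisons are gated on a Shapiro-Wilk test of the differences at
alpha = 0.05: normal-looking differences go to a two-tailed paired t-test,
others to a Wilcoxon matched-pairs signed-rank test (zeros dropped — the
classic variant — exact null distribution up to n = 25 without ties, normal
approximation with continuity correction beyond). The gate decision and the
normality p-value are always part of the result, since which metrics fail
normality varies by dataset. Identical samples short-circuit to p = 1 with a
flag; numerically constant non-zero differences short-circuit to p = 0
(zero-variance shift). Under a pure-noise null the whole gated procedure
rejects at 5% within Monte-Carlo error.

Bland-Altman summaries use differences a - b, the n-1 standard deviation and
1.96-sd limits of agreement; for signed STV analyses pairs are oriented
(method, manual reference) so the bias reads as the method's systematic
offset.

# Problem sizes and numerical choices

The bundled study sizes — 40 phantoms of 40 x 64 x 64 voxels split 30/10,
10 slices per volume, 300 training slices, 10 epochs — were chosen so the
complete experiment (generation, training, prediction, reconstruction,
evaluation) runs in about three minutes on a single core, which makes the
full pipeline practical to re-run from scratch in tests and scripts.
Tolerances used in the checks: 1e-12 for algebraic identities (metric
formulas, pooling), 1e-9 for geometric oracles (distances, rigid-motion
invariance), 0.5–5% for discretization-limited agreements (polygonal prisms,
voxelized ellipsoids), and two-sided Monte-Carlo bands for stochastic
calibrations. Ties in max-pooling route the gradient to the first maximal
element; ties in largest-contour selection keep the first in scan order —
both documented so runs are bit-reproducible.

# Known limitations

* The phantom's realism is qualitative (hypoechoic target, bright bands,
  shadows, speckle); no claim is made that performance on phantoms predicts
  clinical performance.
* One target per volume; branching or merging cross-sections are not
  stitched (the largest component per slice wins).
* The pure-R network engine is CPU-bound; the clinical-scale recipe (60,000
  optimizer steps) is expressible but impractical without hours of compute.
* Signed 3D distances use mesh vertices as the predicted point set; very
  coarse meshes under-sample the surface between slices.
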