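# synovol

Automatic synovial tissue volume (STV) estimation from 3D ultrasound of the
first carpometacarpal (CMC1) joint.

Synovitis — inflammation and hypertrophy of the joint's synovial membrane —
is a key marker of osteoarthritis progression, and on ultrasound it appears
as a hypoechoic region between the bright bone surfaces of the trapezium and
first metacarpal. Quantifying its volume from a 3D sweep normally means a
trained rater outlining the region on every 2D slice, 10–20 minutes per
volume. `synovol` implements the automatic pipeline for researchers working
on musculoskeletal ultrasound quantification:

1. **Slice segmentation** — trainable 2D U-Net / U-Net++ networks (compact
   reverse-mode engine in vectorized base R; no deep-learning framework
   needed) predict a binary synovial mask per transverse slice.
2. **Surface reconstruction** — per-slice sub-pixel boundary contours are
   resampled by arc length, matched across adjacent slices by
   least-squares cyclic alignment, stitched into a triangle mesh, and
   closed with end caps; the STV is the enclosed volume by the divergence
   theorem, exact for the polyhedral surface:

   `V = | Σ_faces det(v1, v2, v3) | / 6`

3. **Evaluation** — precision, recall, accuracy, Dice (DSC = 2TP/(2TP+FP+FN)),
   mean surface distance and Hausdorff distance in mm with signed variants,
   and area/volume percent difference against the manual reference.
4. **Agreement statistics** — Shapiro-Wilk-gated paired t / Wilcoxon
   matched-pairs tests and Bland-Altman bias with 1.96·SD limits of
   agreement.

Because the clinical dataset the method was developed on is not publicly
deposited, the package ships a seeded synthetic-phantom generator (speckled
volumes with bone-like bands, shadows, and crescent- or ellipsoid-shaped
hypoechoic targets with known ground truth, plus a simulated second rater)
so the complete pipeline is testable and reproducible end to end.

## Worked example

```r
library(synovol)

# a full desk-scale study: 40 phantoms (30 train / 10 test), 10 transverse
# slices each, depth-2 8-filter U-Net, ~3 minutes on one core
cfg <- run_config(seed = 1, out_dir = "run1")
res <- run_experiment(cfg)

mean(res$per_slice$unet$dsc, na.rm = TRUE)   # held-out 2D Dice
#> [1] 85.14273
colMeans(res$per_volume$unet[c("dsc", "avpd", "msd", "hd")])
#>        dsc       avpd        msd         hd
#> 89.7927800 11.2653000  0.1852524  1.6456430
res$bland_altman$unet
#> <bland_altman_summary> [STV (cm^3), method - manual] n = 10,
#>   bias -0.001132, sd 0.003022, LoA [-0.007054, 0.004790]
```

After ten epochs on 300 synthetic slices the network segments held-out
phantoms at a mean 2D Dice of 85.1%; stitching the predicted contours into
closed surfaces gives 3D Dice 89.8%, a mean surface distance of 0.19 mm, and
volume estimates within 11.3% of the manual (ground-truth) reconstruction on
average, with a Bland-Altman bias of about −0.001 cm³ — i.e. the automatic
STV tracks the reference with no meaningful systematic offset at phantom
scale.

Individual stages are available directly:

```r
ph  <- generate_phantom(phantom_params(seed = 7))      # image + ground truth
roi <- roi_from_label(ph$label, margin = 15)           # clinical-style ROI
rec <- label_to_surface(ph$label)                      # stitched surface
rec$volume_mm3                                         # enclosed STV in mm^3
rater2 <- simulate_second_rater(ph$label, rater_perturbation(1.5, 0, seed = 2))
evaluate_pair_3d(rater2, ph$label)                     # full metric record
```

A thin command-line front end with `phantom`, `split`, `train`, `predict`,
`reconstruct`, `evaluate`, `compare` and `run-all` subcommands is installed
at `inst/scripts/synovol`.

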