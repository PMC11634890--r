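# bandseg

Shape-prior, narrow-band boundary segmentation for noisy 2-D grayscale
images — built for the canonical hard case of delineating the prostate in
transrectal ultrasound (TRUS), where speckle, shadow artifacts and low
contrast defeat plain pixel classifiers, but the target is a smooth,
star-convex, hypoechoic (darker-inside) region whose shape statistics are
learnable.

It is aimed at researchers in medical image analysis who want a fast,
training-light, fully deterministic segmenter with every stage inspectable:
a statistical shape model, an explicit boundary search space, and a
transparent outlier-repair step, rather than an end-to-end network.

## Method

1. **Shape prior.** Training contours (N landmarks each) are Procrustes
   aligned and a point distribution model is fitted: mean shape x̄, biased
   covariance `Cov = (1/n) Σ (xᵢ − x̄)(xᵢ − x̄)ᵀ`, and the smallest t leading
   eigenmodes P whose eigenvalue fraction exceeds μ (default 0.95). Any
   shape in the model is `x̂ = x̄ + P s`.
2. **Placement.** A 4-parameter affine transform (translations tx, ty and
   axis scales t1, t2) places the mean shape; a moment-based initializer
   estimates it from the dark region's centroid and second moments, or a
   user-supplied transform is plugged in.
3. **Narrow band.** At each of the N prior points, 2L gray values are
   sampled bilinearly at unit steps along the outward normal (offsets
   −L..−1, 1..L; defaults N = 100, L = 30), forming the N × 2L gray matrix
   the rest of the pipeline operates on.
4. **Boundary proposal (NNVO).** Per profile, the offset maximizing the
   outer-minus-inner windowed gray difference, with the score pooled over a
   cyclic window of 10 neighbouring profiles before and 5 after.
5. **Bidirectional denoising (ETSD).** The offset sequence is smoothed by a
   bias-corrected exponentially weighted average with dynamic decay
   `λ_k = min(λ0, (1+k)/(10+k))`, λ0 = 0.9; points flagged by a turning-angle
   test (|θ| > π/4) are pulled to the smoothed sequence with weight α = 0.9,
   normal points keep weight α on their raw value; a second pass runs in
   reverse. The repaired offsets are mapped back along the normals and
   rasterized.

Segmentation quality is reported as Dice, IoU, false-positive rate, and
mean/max absolute point deviation (Mean-AD / Max-AD). A phantom generator
produces TRUS-like test images (harmonic star-convex region, unit-mean
gamma speckle, shadow wedges, boundary-adjacent bright patches) with exact
ground truth.

## Worked example

```r
library(bandseg)

# shape prior from 50 generated training contours
fam   <- generate_shape_family(50, phantom_spec(), seed = 11)
model <- fit_point_distribution_model(procrustes_align(fam)$aligned, mu = 0.95)
model
#> <shape_model: 100 points, 50 shapes, 3/200 modes (mu = 0.95)>

# a speckled phantom with exact ground truth, then the full pipeline
ph  <- generate_phantom(phantom_spec(seed = 3))
res <- segment_image(ph$image, model)          # placement is automatic

om <- overlap_metrics(res$mask, ph$mask)
md <- contour_mad(res$contour, ph$contour)
sprintf("Dice %.4f | IoU %.4f | FPR %.5f", om$dice, om$iou, om$fpr)
#> "Dice 0.9832 | IoU 0.9669 | FPR 0.00144"
sprintf("Mean-AD %.2f px | Max-AD %.2f px", md$mean, md$max)
#> "Mean-AD 3.04 px | Max-AD 9.26 px"
```

The model retains 3 modes: the training family plants exactly three
harmonic modes of variation, and the 95 % variance rule recovers them. The
Dice of 0.983 means the predicted and true masks overlap almost completely;
the Max-AD of 9.3 px (within the L = 30 band) is dominated by the sector a
shadow wedge crosses. `res$diagnostics` exposes the fitted transform,
per-stage offset sequences, anomaly flags and stage timings.

A thin command-line front end with `train-shape`, `segment`, `eval`,
`phantom` and `ablate` subcommands is installed at
`inst/cli/bandseg.R` (`system.file("cli", "bandseg.R", package = "bandseg")`).

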