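---
title: "Shape-prior narrow-band segmentation: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-prior narrow-band segmentation: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandseg)
```

## The problem and the method

Transrectal ultrasound (TRUS) images of the prostate are low-contrast,
speckle-dominated, and prone to shadow artifacts, yet the anatomy itself is
cooperative: the gland is a roughly elliptical, hypoechoic (darker than its
surround) region with a smooth boundary and a fairly predictable position.
`bandseg` exploits exactly that structure. Instead of classifying every
pixel, it:

1. **learns a statistical shape prior** — a point distribution model (PDM)
   built from Procrustes-aligned training contours and a principal component
   analysis of the aligned landmark vectors;
2. **places the prior** on the target image with a four-parameter affine
   transform (two translations, two axis scales);
3. **restricts the search to a narrow band**: at each of the N prior points,
   2L gray values are sampled at unit steps along the outward normal
   (offsets −L..−1, 1..L; the center sample is excluded), giving an N × 2L
   gray matrix that is the only data the segmenter ever looks at;
4. **proposes one boundary position per normal** by maximizing the
   cumulative gray difference between the samples just outside and just
   inside a candidate offset, pooled over a cyclic window of neighbouring
   normals (the neighbourhood normal vector operator, NNVO);
5. **repairs the offset sequence** with a bidirectional, bias-corrected
   exponentially weighted smoother (ETSD) in which curvature-flagged
   outliers are pulled strongly toward the smoothed sequence while ordinary
   points keep most of their raw value.

The final offsets are mapped back to image coordinates along the same
normals and rasterized with an even-odd polygon fill.

## The shape model

Training contours are resampled to N points at uniform arc length (starting
at each contour's stored first point, which also fixes the sequence origin
the smoother uses), oriented counter-clockwise, and aligned by generalized
Procrustes analysis with uniform weights: centering, scaling to unit
centroid size, and rotation onto the evolving mean until the summed squared
residual stops decreasing. The PDM then takes the arithmetic mean of the
aligned 2N-vectors and the eigenvectors of their **biased (1/n) covariance
matrix**; the biased normalization is retained deliberately, matching the
method's published formulation rather than the unbiased 1/(n−1) convention.
The retained mode count t is the smallest number whose cumulative
eigenvalue fraction strictly exceeds μ (default 0.95, the low end of the
usual 95–98 % range).

Two details are worth making explicit:

* **No tangent-space projection** is applied after alignment. For the
  small shape variation this method targets the curvature of the
  pre-shape sphere is negligible relative to the band half-length.
* Scale normalization is non-linear, so a family of shapes generated by
  *linear* landmark displacements is only approximately low-rank after
  alignment. When exact rank recovery matters (as in the tests), the PDM
  can be fitted directly to same-pose contours; the pipeline itself always
  aligns first.

## Localization

The published method uses a small CNN to regress the affine placement; its
training data and supervision are external to this package, so the
operation boundary accepts any `transform_localization` and ships a
training-free default: the image is smoothed (σ = 8 px), thresholded midway
between its 2 % and 98 % intensity quantiles, and the dark region's
centroid and second central moments give the translation and the two axis
scales (compared against the mean shape's analytic polygon moments).
Stray dark pixels from shadow artifacts are trimmed by iteratively keeping
only pixels within 2.2 standard deviations of the running centroid — a
uniform elliptical region has half-axis 2 sd, so the gate never eats the
target itself. There is no rotation parameter; residual rotation is
absorbed by the shape modes. Placement only needs to be good to within the
band half-length: the pipeline's own tolerance study (and the published
method's) shows translation errors of L/2 px change suite-mean Dice by
well under 0.02.

Sub-pixel sampling everywhere uses the bilinear kernel
`I'(i) = Σ_n Σ_m I[n,m] · max(0, 1−|x_i−m|) · max(0, 1−|y_i−n|)`.
Coordinates outside the image are **clamped to the nearest edge pixel**
rather than evaluating to zero as the kernel would literally give: a zero
return would paint artificial dark rims into bands near image borders and
bias the operator there. Pixel centers sit at integer (row, col) with the
top-left pixel at (1, 1).

## The boundary operator

At candidate offset i on profile k the objective is the gray mass just
outside minus the gray mass just inside, over windows of `half_window`
samples per side (default: the full half-band L). Windows are truncated at
the band ends, and each window sum is **divided by its sample count**.
The normalization matters: with raw sums, a truncated window loses mass
purely because it is shorter, which systematically drags the argmax toward
the band center — on clean phantoms this bias alone cost several pixels of
accuracy. Where both windows are complete the normalized score is the
plain windowed sum divided by a constant, so the argmax is unchanged
there. The exported `cumulative_gray_difference()` keeps the strict plain
sum contract and refuses windows that leave the band.

NNVO pools the per-profile scores over a cyclic neighbour window before
the argmax; the default window of 10 profiles before and 5 after is the
operating point established experimentally for N = 100. Pooling is what
suppresses single-profile outliers (a bright speck corrupts one profile,
but fifteen neighbours out-vote it); its cost is a consensus bias of
roughly a pixel on strongly curved boundaries, visible in the ablation
as a small Mean-AD gap between the plain operator and NNVO on noiseless
phantoms. Ties are broken toward the offset closest to zero and then
toward the inside: absent evidence, the prior is the best guess.

## The denoiser

The offset sequence along the contour is treated as a time series. The
smoother maintains a zero-initialized accumulator
`m_k = λ_k m_{k−1} + (1−λ_k) x_k` and divides by `1 − Π_{j≤k} λ_j`, the
exact normalizer of its weights. Written this way the smoother is a true
convex combination of the prefix inputs — the first output equals the
first input, constants are preserved, and for fixed λ the correction
reduces to the familiar `1 − λ^k`. The literal published recursion feeds
the *corrected* value back into the accumulator, which breaks range
preservation (a constant input c maps to c/(1−λ²) at the second step);
the accumulator form is the only self-consistent reading and is what this
package implements. The decay follows `λ_k = min(λ0, (1+k)/(10+k))`
(default λ0 = 0.9): early in the sequence little history exists, so the
raw samples dominate.

Outliers are flagged by the turning angle at each reconstructed contour
point (difference of the two segment directions over a stride `k_step`,
wrapped to (−π, π]); a point turning more than `curvature_threshold`
(default π/4 — the published method derives its band from ground-truth
statistics it does not print, so a fixed threshold stands in, exposed in
the configuration) is pulled toward the smoothed sequence with weight α
(default 0.9), while normal points keep weight α on their raw value. The
smoothing acts on the 1-D signed offsets, not on raw coordinates —
offsets are what the operator produced and what the band constrains —
while the curvature is measured on the reconstructed 2-D contour, where
geometry lives. A second, backward pass (the reversed forward pass)
repeats detection and fusion so that information flows both ways along
the contour; the closed contour is treated as an open sequence per pass.
Final offsets are clamped to the band. Exactly two passes are run.

## The phantom generator

All tests and the acceptance study run on synthetic phantoms with exact
ground truth, standing in for clinical data that cannot be bundled. A
phantom is: a star-convex region `r(φ) = R(1 + Σ_h a_h cos(hφ + ψ_h))`
(default R = 140 px, harmonics 2–4 with relative amplitudes 0.06, 0.03,
0.015, phases drawn from the seed) on a 576 × 768 frame; interior level 60
against surround 150; mild wedge shadows (two sectors, 25 % attenuation);
fully developed speckle as **unit-mean multiplicative gamma noise**
(shape 10, i.e. ~32 % intensity CV — the standard approximation; the real
speckle statistics of any particular scanner are not modeled); Gaussian
blur σ = 2; and four bright Gaussian patches (amplitude 140, σ = 5 px)
placed just inside the boundary, where they flip the local contrast and
reliably induce operator outliers. The ground-truth mask is the exact
sub-pixel inequality at pixel centers and the contour samples the same
radial function at N = 100 uniform angles.

What the phantoms do **not** emulate: directional speckle correlation,
attenuation with depth, refraction and reverberation artifacts, the fan
geometry of sector probes, and pathology-driven shape departures outside
the prior's span. Passing the phantom suite therefore demonstrates the
mechanics of the method — band search, pooling, outlier repair — not
clinical-grade performance.

The training-shape generator plants exactly `length(mode_sds)` radial
harmonic modes (default SDs 10, 7, 5 px, chosen so the third mode is
needed to pass the 95 % variance threshold: the cumulative shares are
0.57, 0.86, 1.00) on a circular base, displacing landmarks along their
radial unit vectors so the planted modes are mutually orthogonal and a
fitted PDM recovers them exactly.

## Study sizes and numerical choices

The standard study configuration used by the tests and the acceptance
script is 20 phantoms (seeds derived from the run seed) at the default
noise level, one clean phantom, and a 4-variant ablation over the same
suite — sizes chosen to make the statistics stable while the whole study
runs in a few minutes on one CPU. Other numerical choices: Procrustes
stops when the residual decrease falls below 1e−10 (cap 100 iterations);
eigenvalues are clipped at zero before the retention rule; a total
variance below 1e−12 yields a zero-mode model; the rasterizer uses strict
inequality against pixel centers, and its self-intersection check is
waived inside the pipeline because the even-odd rule remains well-defined
on near-degenerate contours. Degenerate inputs (all-coincident shapes,
zero-variance images, windows leaving the band, non-star-convex radial
specs) raise errors rather than returning silently wrong values.

## Known limitations

* The method assumes a star-convex, darker-inside target; bright-inside
  structures need an inverted image.
* Landmark correspondence comes from uniform arc-length resampling, so
  Mean-AD/Max-AD conflate boundary error with tangential slippage; the
  overlap metrics (Dice, IoU, FPR) are correspondence-free.
* Boundaries that leave the ±L band around the placed prior are
  unreachable by construction; that is the price of the narrow-band
  speed and noise immunity.
* The neighbour window [−10, 5] is asymmetric by design (it was tuned
  for N = 100 in the published experiments); for very different N it
  should be rescaled.
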