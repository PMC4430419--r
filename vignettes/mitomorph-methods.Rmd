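---
title: "Methods: mitochondrial network morphometry and assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial network morphometry and assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each step, the parameters that matter, and the choices
made where more than one reasonable definition exists. It states no
empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The measurement problem

Mitochondrial networks in *C. elegans* body-wall muscle, imaged by confocal
microscopy of a matrix-targeted GFP, respond to mitotoxic drugs in two
opposite directions: hyperfusion into long tubules, or fragmentation into
small blobs. The quantification task is to turn a multi-slice fluorescence
stack into a small vector of interpretable descriptors per image, compare
them across treatment conditions, and cluster conditions into phenotype
classes. Alongside imaging, the same studies quantify mtDNA copies by qPCR
against a plasmid standard curve, oxygen consumption from respirometer
traces, and the coenzyme Q9 redox state from HPLC peak areas. The package
implements each of these with explicit, testable semantics.

## Segmentation pipeline

`run_pipeline()` composes seven stages; each is exported on its own.

**Slice triage.** Deep slices in a stack are defocused or contain
reflections; they would dilute a maximum projection. Each slice is scored
by the population variance of its pixel intensities (squared native gray
units) and retained when the score exceeds `qc_threshold` (default 1). A
perfectly uniform slice scores 0. Variance is one natural reading of a
single-image "covariance" quality score; since other readings exist, the
statistic is logged per slice and the threshold is a parameter. Rejecting
every slice is an error, not an empty result.

**Maximum-intensity projection.** Pixel-wise maximum over retained slices;
exact by construction, and checked against a brute-force loop in the tests.

**Rolling-ball background subtraction** (`ball_radius_px = 15`). The
background is the grayscale opening of the image by a hemispherical
structuring element: an erosion `min_d(f(x+d) − h(d))` followed by a
dilation, with `h(d) = sqrt(r² − d²)`. Structures narrower than the ball
cannot hold the ball up and are excluded from the background, hence
preserved after subtraction; output is clipped at zero. The operation is
anti-extensive (never exceeds the input) and invariant to adding a
constant offset. A ball larger than the image degrades gracefully to a
global-minimum background with a warning. Note one discretization effect:
a 1-px spike retains a residue of `h(0) − h(1)` (≈ 0.03 gray levels at
radius 15) in its background estimate, i.e. the value is preserved to
within 0.1 %.

**Local contrast enhancement** (`block_size_px = 15`, `clip_limit = 3`).
Contrast-limited adaptive histogram equalization over tiles of roughly the
block size, delegated to `EBImage::clahe` (tile counts are derived from
the block size; the image is edge-padded to a tile multiple and cropped
back). The clip limit bounds the slope of the transfer function so flat
background is not amplified into structure. The value 3 is the common
ImageJ default; it is exposed as a parameter. If the block exceeds the
image, global equalization is used with a warning; a constant image is
returned unchanged.

**Multi-scale Laplacian enhancement** (`scales_px = c(1, 2)`). For each
scale σ the image is convolved with the scale-normalized
Laplacian-of-Gaussian `σ²∇²G_σ` (zero-sum kernel, replicate borders); the
negated responses are combined by pixel-wise maximum and clipped at zero,
so bright tubules and blobs produce ridges and peaks of comparable
magnitude across widths. The matched scale of a cylindrical structure of
radius ρ is about ρ/√2; at 0.2 µm/px, mitochondrial tubules and fragments
of 0.4–1 µm diameter correspond to σ ≈ 1–2 px, which fixes the default
scale set. Including a σ = 4 scale was evaluated and rejected: its
response is positive in a wide halo around thin structures, inflating
masks by roughly half and bridging distinct objects into single
components, which measurably degrades object-level recovery on simulated
networks. The scale set remains a parameter for coarser imagery.

**Yen autothresholding.** The threshold maximizes Yen's
maximum-correlation criterion, computed from a 256-bin histogram spanning
the observed intensity range (the same binning for all bit depths). For a
split with cumulative probability `P1` and cumulative squared
probabilities `S1`, `S2`, the criterion is
`2·ln(P1(1−P1)) − ln(S1·S2)`; ties break toward the lowest threshold, and
the mask is `img > threshold`. The enhanced (Laplacian) response is
thresholded by default — enhancement precedes binarization — with
`threshold_input = "contrast"` available to threshold the equalized image
instead. A constant image raises a "degenerate histogram" error. The
implementation (cumulative sums) is checked against exhaustive
criterion evaluation on random histograms.

**Object extraction** (`min_size_px = 12`, `connectivity = 8`). Connected
components of the mask, strictly larger than 12 px (a 12-px component is
removed), renumbered in raster order. Eight-connectivity is the ImageJ
particle-analysis convention; 4-connectivity is available.

Per-object intensity and whole-image texture are measured on the
*unenhanced* maximum projection, which `run_pipeline()` returns alongside
the objects for exactly this purpose.

## Shape and texture descriptors

All descriptors use row-major, pixel-center geometry.

- **Ellipse fit**: second central moments with the 1/12 unit-pixel-square
  correction, axes scaled so the ellipse area equals the pixel count
  (the ImageJ "fit ellipse" convention). `AR` is major/minor; `Round` is
  `4A/(π·major²)`, which for an ideal ellipse reduces to minor/major.
- **Perimeter**: the outer boundary is traced (Moore neighborhood) and the
  chain is weighted 0.948 per axial and 1.340 per diagonal step — the
  corrected boundary-step estimator, which is near-unbiased on smooth
  digital contours. The naive 1/√2 weighting overestimates a circle's
  perimeter by ~5 %, which would bias circularity of a large disk to
  ≈ 0.90; with the corrected weights the disk limit is ≈ 1, as the tests
  assert. `Circ = 4πA/P²` is capped at 1.0.
- **Feret diameter**: maximum pairwise distance between boundary-pixel
  centers, computed over the convex hull for speed and checked against the
  O(n²) scan. One-pixel objects are flagged degenerate (Feret 0, unit
  shape descriptors).
- **Solidity**: pixel count divided by the number of pixel centers inside
  (or on) the convex hull of the object's pixel centers — a rasterized
  hull, so solidity never exceeds 1. (The polygon area of a corner-based
  hull systematically exceeds the rasterized area on convex shapes, which
  would bias a disk's solidity to ≈ 0.95.)
- **GLCM texture**: intensities are binned linearly over the full
  bit-depth range (256 levels by default; 64 recommended for 16-bit
  input), pairs are counted at the one-pixel horizontal and vertical
  offsets (asymmetric by default), normalized, and the three features are
  evaluated exactly as their defining sums with natural logarithms and
  `0·ln 0 = 0`. Correlation is reported as the standard Haralick form
  `Σ P_ij (i−μ_i)(j−μ_j)/√(σ_i²σ_j²)`; it is `NaN` (flagged, not zeroed)
  when a marginal variance vanishes, e.g. on a constant image.
- **Per-image record**: per-object metrics are averaged unweighted
  ("average values" semantics; area-weighted averaging is available behind
  a flag), texture features are the mean of the horizontal and vertical
  values, and `NObjects` is recorded. Zero-object images yield a flagged
  record that the clustering front-end excludes.

## Phenotype analysis

Feature tables are z-scored per column (sample SD; constant columns are a
named error). The clustergram applies UPGMA (average linkage) with
Euclidean distance to rows and columns; merge heights equal average
inter-cluster distances, verified against a brute-force O(n³)
agglomeration in the tests. Dendrograms export to Newick with
heights-derived branch lengths. k-means uses Lloyd's algorithm with
seeded random restarts (best of `n_init` by within-cluster sum of
squares), so results are bit-reproducible for a fixed seed.

Two details were genuinely open:

- **Rows to cluster.** Whether the clustergram operates on per-image rows
  or per-condition means is not fixed by the workflow itself. The default
  is per-condition means (`by = "condition"`), which is what a clustered
  condition heatmap displays; per-image mode is available and is what the
  k-means recovery checks use.
- **t-test flavors.** Morphology metrics are compared with Welch
  (unequal-variance) t-tests, gated per group by Shapiro-Wilk at α = 0.05
  with a Wilcoxon rank-sum fallback; groups too small for Shapiro-Wilk
  (n < 3) or with zero variance go to the rank-sum branch. The qPCR module
  instead implements the classical pooled-variance t statistic, matching
  its use alongside the pooled SD in quantification; both flavors are
  exported. No multiple-testing correction is applied by default
  (per-metric asterisks convention); Holm correction is behind a flag.

## qPCR quantification

The standard curve is an ordinary least-squares fit of Ct on
log10(copies) from a tenfold plasmid dilution series. Absolute
quantification inverts the mean Ct through the curve
(`copies = 10^((Ct − intercept)/slope)`, requiring slope < 0) and scales
to copies per worm by `dilution_factor × (lysate_volume/template_volume) /
worms_per_lysate`. The lysate volume has no universal default and the
per-worm scale depends on it directly, so it is a required argument.

Relative quantification expresses a sample as a percentage of an
unexposed reference, `100 × 10^(ΔCt/slope)`. Its confidence interval
propagates replicate Ct dispersion: a pooled-SD t-interval on ΔCt with
`df = n1 + n2 − 2` (nine replicates against nine gives df = 16), mapped
through the curve, hence asymmetric in percent. This is a documented
choice among several defensible CI constructions; Monte-Carlo coverage at
σ_Ct = 0.2 is checked in the tests.

## Respirometry and redox state

`respiration_rate()` scans all contiguous windows covering at least half
the O₂ trace and fits each by OLS via prefix sums. It keeps the window
with the highest R², breaking ties toward the longer window, and requires
the winner to reach `r2_threshold = 0.99` (otherwise the full trace is
used, with a warning). Selecting by fit quality rather than "longest
window above the threshold" matters: with a mild equilibration transient,
the full trace can still exceed R² = 0.99 while its slope is biased by
several percent, whereas the best-fitting window excludes the transient.
The rate is the negated slope divided by protein mass; rising traces are
flagged. `redox_ratio()` is the ubiquinol percentage of the quinone pool,
`100·reduced/(reduced + oxidized)`, from pre-integrated peak areas —
chromatogram peak detection is out of scope.

## The simulators: what they emulate, and what they do not

`simulate_network_stack()` renders three phenotypes on a 160×160 frame at
0.2 µm/px, 8-bit: *tubular* (20 long persistent random-walk filaments,
mean length 80 px, persistence 0.92), *control* (30 semi-aligned filaments
of intermediate length, mean 25 px, orientation jitter 0.35 rad about a
shared axis, emulating the pseudo-parallel muscle architecture), and
*fragmented* (45 rasterized ellipses, radius ~3 px, mild eccentricity).
Filaments are dilated to ~3 px width. The clean scene is spread over three
in-focus slices with triangular focus weights, blurred by a Gaussian PSF
(σ = 1 px), and corrupted by Poisson shot noise plus Gaussian read noise
splitting the total noise power equally, scaled so peak signal over total
noise SD equals `snr` (default 10). Two defocused slices (heavy blur
toward the background, near-uniform) are appended at the stack ends so the
triage stage has genuine rejects; by construction their variance falls
below 1 while in-focus slices lie far above. All randomness flows through
one seed (`withr::with_seed`), leaving the global RNG untouched.

Ground-truth labels are the 8-connected components of the union of
rendered structures: structures that touch or cross merge into one true
object, which keeps the mask/label invariant exact and makes object-level
precision/recall well defined. Per-structure generator parameters are
retained separately.

Deliberate non-realism: no 3-D network topology (the analysis operates on
projections), no photobleaching, no spatially varying background or
illumination, no camera fixed-pattern noise, single channel only. Passing
tests therefore demonstrate correctness of the operators and recovery
under idealized image formation — not robustness to every artifact of
real acquisitions.

The remaining generators are direct: feature tables as
`baseline + class shift + N(0, sd)` per metric; Ct values on the
log-linear curve with Gaussian cycle noise; O₂ traces as a linear decline
with optional exponential equilibration transient and Gaussian noise.

## Problem sizes and numerical tolerances

The test suite and acceptance script use 160×160 stacks, 10 seeds per
phenotype for segmentation recovery, 30-image three-class experiments for
clustering, 100 simulated standard curves for CI coverage, and 10,000
null replicates for test calibration — sizes chosen to give stable Monte
Carlo estimates while keeping a full run in the low minutes on one CPU.
Exact computations (projection, GLCM, Yen, Feret, UPGMA) are compared to
brute-force oracles at tolerances of 1e-10 or tighter; analytic shape
limits on rasterized shapes use 5 % bands reflecting discretization;
detection F1 uses an IoU ≥ 0.3 match threshold.

## Known limitations

- At low SNR (≈ 5), large tubular networks fragment under per-pixel
  thresholding: thin dim stretches drop below the Yen threshold and a
  single true network splits into several components. Object-level
  recovery degrades accordingly; the default simulator SNR of 10 reflects
  a reasonably exposed confocal acquisition.
- Skeleton-based topology metrics (branch points, edge lengths) and 3-D
  morphometry are out of scope by design.
- The triage statistic, CLAHE clip limit, LoG scale set and GLCM level
  count are pragmatic defaults for 8-bit confocal imagery at 0.2 µm/px;
  coarser pixel sizes or 16-bit ranges warrant revisiting them (all are
  parameters).
- Amplification efficiency is assumed log-linear over the dilution range;
  efficiency-correction models and multi-gene normalization are not
  implemented.
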