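---
title: "Methods: quantifying wing colour-pattern mimicry with wingmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying wing colour-pattern mimicry with wingmatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmatch)
```

## Overview

`wingmatch` quantifies how similar the wing colour patterns of two groups
of butterflies are, separating two questions that are usually conflated:
do the patterns occupy the same *amount* of wing, and do they occupy the
same *place*? The pipeline is: landmark-based thin-plate-spline (TPS)
registration into a common reference frame, RGB-threshold pattern
extraction, population-level aggregation (frequency maps, difference maps,
mismatch statistics), PCA over binary pattern rasters with group
statistics, and quantification of knockout (KO) phenotypes via consensus
contours and affected-area overlap. This vignette documents the model,
its assumptions, the tunable parameters, the numerical choices, and what
the synthetic validation data can and cannot establish.

## Registration model

Every wing carries K ordered landmarks at homologous vein intersections
(K = 11 by default; the count is enforced, the order *is* the homology).
Registration assumes these landmarks are identifiable on every usable
image — there is no automatic landmark detection and no segmentation of
wings from raw photographs.

The TPS transform uses the standard kernel `U(r) = r² log r` with
`U(0) = 0`. For each output dimension the mapped coordinate is an affine
part plus kernel terms centered on the source landmarks, with weights
constrained by the three orthogonality side conditions (`Σw = 0`,
`Σw·x = 0`, `Σw·y = 0`). With regularization `λ = 0` (the default) the
transform interpolates the landmarks exactly; `λ > 0` adds smoothing on
the kernel diagonal and is exposed for noisy landmark digitization.
Affine landmark relations produce zero bending (warp weights vanish to
numerical precision), which the test suite checks on random rotations and
general affine maps.

Masks are resampled into the reference frame by **inverse mapping**: the
TPS is fitted from reference landmarks (source) to sample landmarks
(target) and evaluated at every reference cell center, looking up the
sample mask by **nearest pixel** (out-of-image lookups read 0). Inverse
mapping is hole-free at any grid resolution, and nearest-pixel sampling
keeps masks binary without introducing a second threshold. Whether an
original patternize-style workflow warps forward or resamples inversely
can differ cellwise near boundaries; this package commits to the inverse
convention throughout.

### Grid conventions

One convention is used everywhere to avoid off-by-one drift: 0-based
continuous coordinates, origin top-left, y increasing downward; grid cell
(row r, col c) has its center at
`(xmin + (c − 0.5)·dx, ymin + (r − 0.5)·dy)`; a cell belongs to a polygon
iff its center is inside by the even-odd rule; all areas are cell counts.
Reference-frame bounds default to the reference-landmark bounding box
expanded 25% per side, and the default grid is 150 × 150 — the source
methodology never states a raster resolution, so it is configuration
here; 150² keeps the PCA matrices small while oversampling the wing
relative to typical landmark spacing. A pixel-matched frame (one cell per
reference pixel) is available via `population_frame(pixel = TRUE)` for
analyses where grid quantization of small regions matters, e.g. measuring
KO-affected patches of only a few percent of the wing.

The wing outline must be supplied as a polygon: it is not derivable from
11 vein landmarks, and the relative-area statistic needs a defined "total
wing area". Cells outside the outline are missing (`NA`), never counted.

## Pattern extraction

A pixel matches a colour spec when every channel lies within
`round(offset × 255)` of the target RGB (Chebyshev box). The box metric is
monotone in the offset and cheap to reason about; Euclidean RGB distance
is available as an alternative (`metric = "euclidean"`). Multi-colour
patterns extract as the union over specs, so a red + white band is one
pattern. Colour targets and offsets are per-morph configuration — the
original study chose them per phenotype and never published them, so they
are free parameters; the synthetic generator emits its own targets as
ground truth. Damaged or noisy regions are removed by exclusion polygons
(pixels inside any polygon are forced to 0; the operation is idempotent).
No colour-space conversion, UV information or scale-level texture is
modelled.

## Aggregation and mismatch statistics

For a population of aligned binary rasters the frequency map is the
cellwise mean; the difference map between two groups is `f_A − f_B`
(positive = more pattern in group A, drawn red; negative = group B,
blue). Two comparable summaries on [0, 1]:

- **absolute mismatch** = mean over within-wing cells of `|f_A − f_B|`
  (area-normalized so it shares an axis with the next quantity — the
  source figures plot both on one axis without stating a normalization);
- **relative-area difference** = `|mean(area_A) − mean(area_B)|` of
  per-sample relative pattern areas.

The observation units for testing are a documented interpretation rather
than a published procedure: the per-sample mismatch of sample *i* in group
A is the mean of `|bᵢ − f_B|` over within-wing cells (and symmetrically),
fed to a one-sample t-test against 0; per-sample relative areas feed a
Welch two-sample t-test. Welch is the default because the original
reporting is silent on variance assumptions; a pooled-variance option
exists for exact replication attempts. No multiple-testing correction is
applied across pairwise comparisons by default (matching the original
reporting style); Holm adjustment is available in the pipeline
configuration. No spatial autocorrelation correction is attempted on
per-cell maps.

## PCA on binary rasters

The sample × cell matrix over within-wing cells (missing cells dropped
from the feature vector, not zero-filled — zero-filling would manufacture
shared "absence" variance) is centered by the cellwise mean and
decomposed by SVD; with ~10⁴–10⁵ cells and tens of samples, an explicit
covariance eigendecomposition is not tractable and SVD is exact.
Numerical choices:

- zero-variance cells (pattern present in all samples, or in none) are
  excluded before the SVD and written back as exactly-zero loadings;
- axis signs are fixed so each loading's largest-magnitude element is
  positive (SVD is otherwise sign-ambiguous);
- `predict_pattern(model, axis, score)` returns `score × loading`, other
  axes at zero, clipped to [−1, 1] for display.

"Significant axes" default to the **broken-stick** criterion (retain the
leading axes whose variance ratio meets the broken-stick expectation; the
boundary case of an axis exactly on the stick — e.g. one axis carrying
100% of variance — is retained). The original criterion lived in an
unavailable supplement, so broken-stick was chosen as a standard,
parameter-free rule; cumulative-threshold and fixed-k selection are also
provided, and retained-axis counts may legitimately differ from the
original analysis.

MANOVA on retained axes reports Pillai's trace (robust default) with
Wilks' lambda alongside, since the original statistic is unnamed; a
single retained axis reduces exactly to the one-way ANOVA. Whether
published F values with one numerator df came from univariate ANOVA or a
1-D MANOVA is unknowable from the text — both paths exist
(`per_axis_anova`, `manova_scores`) and coincide in 1-D. LDA uses pooled
covariance and proportional priors; the evaluation default is
leave-one-out, because resubstitution inflates posteriors and the
original scheme is unstated.

Degenerate inputs are reported, not silently computed: zero-variance
t-tests raise errors; one-way ANOVA with zero within-group variance but
distinct means returns an explicitly "degenerate" result with an infinite
statistic; singular covariance in MANOVA/LDA raises a rank error that
suggests retaining fewer axes.

## KO quantification

The consensus KO pattern is the set of cells present in at least 50% of
KO wings (threshold configurable), traced at the 0.5 isoline by marching
squares with linear interpolation; the grid is padded with a zero ring on
the frame bounds so every contour closes inside the frame. "Affected
area" per KO wing is the **symmetric difference** against the wild-type
consensus (built by the same ≥ 50% rule — symmetric treatment, with a
single-reference option), restricted to the wing outline, as a percentage
of within-outline cells; gain-only and loss-only sub-reports are emitted
because knockouts can both expand and retract pattern. Left and right
wings are treated as independent observations by default (mirroring a
10-wings-from-5-individuals design); whether published mean ± sd values
were taken across wings or individuals is not stated, so across-wings is
the default and per-individual averaging is left to the caller. Mosaic or
partial-KO phenotypes are out of scope.

## The synthetic generator

`generate_population()` renders what the pipeline needs and nothing more:
a smooth parametric forewing outline, 11 fixed landmark anchors, a
mid-forewing band of one of three archetypes — solid "postman" band,
"split" two-spot (white + red), "broken" three-spot (yellow) — flat
colours with hard edges, optional Gaussian pixel noise, and optional
damage blotches recorded as exclusion polygons. Per-individual variation
is a smooth TPS warp (a 3 × 3 control grid displaced by Gaussian noise)
applied jointly to outline, band and landmarks, plus independent landmark
digitization noise. The first individual is emitted unjittered and serves
as the common reference sample, mirroring the "arbitrarily chosen
reference" of landmark-based workflows.

Default conditions (chosen once as realistic study conditions): landmark
noise sd 1.5 px and warp amplitude 3 px on a 200-px wing (≈ 1–2% of wing
length, typical of manual digitization), pixel noise sd 4 of 255, damage
off, band covering ≈ 24% of the wing, populations of 8–14 individuals in
examples, extraction offset 0.15 with palette colours separated by more
than twice that offset in Chebyshev distance (enforced by the
constructor). Ground truth is defined as the rendered reference
individual's band pixels sampled at grid cell centers — consistent with
the rendered image by construction, so the zero-noise end-to-end identity
is exact rather than blurred by comparing two different rasterization
paths.

`generate_comimic_pair()` produces the key experimental design: group B's
band is shifted by a stated fraction of wing length and its width is
numerically calibrated (bisection on the rendered mask) so both bands
cover the same wing fraction — equal size, different position. Calibration
is quantized by whole pixel columns, so "equal" areas agree to roughly
half a pixel column (< 1% of band area at the default 200-px width).
`generate_ko_pair()` adds a compact square patch abutting the proximal
band edge, calibrated so the truly gained area is a stated fraction of
the wing.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: photographic lighting variation and colour
gradients, scale-level texture and iridescence, venation, hindwings,
asymmetric or partial phenotypes, landmark placement errors correlated
with wing damage, and interspecific wing-shape differences (wing-shape
control analyses are out of scope). Tests against the generator validate
the *machinery* (registration, extraction, aggregation, statistics), not
the biological parameter choices an analyst must still make for real
photographs (colour targets, offsets, exclusion masks).

## Validation problem sizes

The test suite validates each operation against independent oracles:
brute-force per-cell counting for frequency/consensus/overlap maps,
hand-computed sums of squares and t formulas for the statistics,
`mgcv::in.out` for point-in-polygon, closed-form rotations for TPS, and
full-rank SVD reconstruction for the PCA. Statistical calibration uses
1000 null replicates (type-I error of t/ANOVA at α = 0.05) and 200
replicates of label-shuffled LDA (chance-level posteriors, n = 60). The
end-to-end mismatch experiment uses 20 seeds of 12 + 12 individuals at a
100 × 100 grid with a 6%-of-wing-length band offset; KO recovery uses 10
wild-type and 10 KO wings at 2%, 10% and 20% affected-area fractions on a
pixel-matched frame. These sizes were chosen to exercise the estimators
well inside their asymptotics while keeping the full suite quick to run
on a laptop.

## Known limitations

- Registration quality is bounded by landmark quality; there is no
  Procrustes averaging, landmark sliding, or diffeomorphic refinement.
- The colour model is a hard threshold; patterns whose boundary is a
  colour gradient will be sensitive to the offset choice (the offset is
  monotone, so sensitivity is at least predictable).
- Binary-raster PCA is plain linear PCA despite the binary data (as in
  the methodology this follows); no sparse or logistic PCA is offered.
- Per-cell difference maps are descriptive; no per-cell inference is
  performed.
- The package quantifies patterns; it does not interpret them. Linking
  mismatch maps to developmental territories is the analyst's inference.
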