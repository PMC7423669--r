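# wingmatch

Quantitative analysis of butterfly wing colour-pattern mimicry.

Co-mimetic butterflies such as *Heliconius erato* and *Heliconius melpomene*
converge on shared warning patterns, yet the match is rarely perfect: the
pattern can occupy the same *amount* of wing while sitting in a slightly
different *place*, and CRISPR knockouts of patterning genes (e.g. *WntA*)
reveal species-specific developmental territories that constrain how close
the match can get. `wingmatch` packages the image-analysis pipeline needed
to quantify all of this from wing photographs: landmark-based registration,
colour-pattern extraction, population pattern-frequency maps,
mismatch statistics, pattern PCA, group classification, and knockout
phenotype overlap — plus a synthetic wing-image generator with exact ground
truth so the whole pipeline can be validated end-to-end.

## The method

Each wing photograph carries **K = 11 landmarks** at homologous vein
intersections. A **thin-plate-spline** (TPS) transform with kernel
`U(r) = r² log r` is fitted from the reference sample's landmarks to each
sample's landmarks; sampling the sample image at the inverse-mapped
position of every grid cell center aligns all wings into one reference
frame. The colour pattern (e.g. the mid-forewing band, MFB) is extracted by
RGB thresholding: a pixel matches a target colour when every channel is
within `round(offset × 255)` of it; multiple colours (red + white bands)
are combined by union. On the common grid:

- **frequency map** `f(c) = (1/n) Σᵢ bᵢ(c)` — the proportion of wings in a
  population showing pattern at cell `c`;
- **difference map** `f_A − f_B` — positive where group A has more pattern;
- **relative area** — pattern cells / within-wing cells (the proportion of
  the wing the pattern occupies);
- **absolute mismatch** — mean over within-wing cells of `|f_A − f_B|`,
  which is position-sensitive, directly comparable on [0, 1] to the
  **relative-area difference** `|mean(area_A) − mean(area_B)|`, which is
  position-blind. Their ordering is the headline diagnostic: equal-sized
  but shifted patterns give a large absolute mismatch with a near-zero area
  difference.
- **PCA on binary rasters** (SVD of the centered sample × cell matrix)
  summarizes pattern-boundary variation; `score × loading` reconstructs the
  predicted pattern along an axis (positive cells: predicted presence;
  cells shared by all samples load exactly zero). Retained axes
  (broken-stick by default) feed MANOVA (Pillai) and leave-one-out LDA
  posterior classification.
- **KO quantification**: the consensus knockout pattern is the set of cells
  present in ≥ 50% of KO wings, traced as closed contours; the per-wing
  affected area is the symmetric difference against the wild-type consensus
  as a percentage of the forewing, reported as mean ± sd with gain/loss
  sub-reports, and overlap of KO territories with wild-type difference maps
  is reported as percentages of the forewing.

## Worked example

Two synthetic co-mimic populations with equal band area but a positional
offset of 6% of wing length — the "compensatory" configuration in which
size matches while position does not:

```r
library(wingmatch)

spec <- morph_spec("postman")
pair <- generate_comimic_pair(spec, n_a = 12, n_b = 12, seed = 1,
                              band_offset = 0.06)
frame <- population_frame(pair$pop_a, grid_shape = c(100, 100))
rasters_a <- align_population(pair$pop_a, frame)
rasters_b <- align_population(pair$pop_b, frame)

(ms <- mismatch_summary(rasters_a, rasters_b))
#> <mismatch_summary> n = 12 + 12
#>   absolute mismatch:        0.1581
#>   relative-area difference: 0.0036 (areas 0.2387 vs 0.2352)

one_sample_t(c(ms$per_sample_mismatch_a, ms$per_sample_mismatch_b), 0)
#> <test_result> one-sample t-test: statistic = 23.79, df = 23, p = 1.069e-17
two_sample_t(ms$per_sample_areas_a, ms$per_sample_areas_b)
#> <test_result> Welch two-sample t-test: statistic = 0.8999, df = 16.417, p = 0.3812
```

The populations mismatch strongly in pattern *position* (absolute mismatch
0.158, highly significant) while their pattern *size* is statistically
indistinguishable (area difference 0.004, p = 0.38) — exactly the
compensatory design the generator was asked for. The same rasters feed the
pattern PCA and classification layer:

```r
pca <- fit_raster_pca(c(rasters_a, rasters_b))
axes <- select_axes(pca)   # broken-stick: axes 1, 2
labels <- rep(c("erato-like", "melpomene-like"), each = 12)
manova_scores(pca$scores[, axes], labels)
#> <test_result> MANOVA (Pillai): statistic = 0.9419, df = 2, 21, p = 1.051e-13
lda_classify(pca$scores[, axes], labels)
#> <classification_report> scheme = loo
#>   erato-like: mean posterior for true group 100.0%
#>   melpomene-like: mean posterior for true group 100.0%
```

For file-based workflows, `write_population()` emits a drop-in dataset
(PNG images, landmark CSVs, manifest) and `run_pipeline("config.yaml")`
runs the whole analysis from a configuration file, writing frequency maps,
difference maps, mismatch/statistics tables, PCA scores, KO contours and a
run log into an output directory. A thin command-line wrapper lives at
`inst/scripts/wingmatch-run.R`.

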