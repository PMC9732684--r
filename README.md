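# ielquant

Compartmental quantification of CD3 and γδ T cells in colon mucosa, with
mixed-model group comparisons.

## The problem

Inflammatory bowel disease pathology cares about *where* T cells sit, not
just how many there are: intraepithelial lymphocytes (IELs), the cells in
the narrow zone immediately beneath the basement membrane, and the cells
of the lamina propria behave differently between Crohn's disease and
ulcerative colitis and between histologically active and inactive mucosa
(activity = neutrophils present, Nancy grade 2–4). Counting these cells
per compartment by eye is subjective and slow. `ielquant` implements the
whole quantification chain on calibrated H-DAB images, for pathologists
and image-analysis researchers who want reproducible per-compartment
counts and defensible group statistics:

1. **Colour deconvolution** — per-pixel optical density
   `OD = −log10(max(I,1)/255)` is unmixed into hematoxylin and DAB
   channels with the pseudo-inverse of a unit stain matrix (negative
   concentrations clamped at 0).
2. **Geometry** — a tissue mask from total OD, an epithelium mask from a
   trainable random-forest pixel classifier (or QuPath-style GeoJSON
   annotations), and the subepithelial band as the exact Euclidean 5 µm
   expansion of the epithelium, clipped to tissue. The three labels
   partition the tissue raster.
3. **Cells** — nuclei by smoothed-peak detection plus marker-based
   watershed on the hematoxylin OD landscape; nuclei outside the
   inclusive 125–3,000 px² area range (at the 0.225 µm/px reference
   scale) are discarded; each nucleus is expanded 1.5 µm to a cell
   boundary with a nearest-nucleus split; a seeded three-class random
   forest labels every detection positive / negative / artefact.
4. **Quantification** — counts by the nucleus-centroid rule:
   intraepithelial and subepithelial positives per 100 epithelial cells,
   lamina propria positives per mm², and γδ/CD3 ratios from parallel
   sections. Epithelial + subepithelial + lamina propria counts equal the
   whole-mucosa count exactly.
5. **Statistics** — for counts `y` with denominator `d`, a
   random-intercept model on the natural-log scale

   `log((y + 0.5)/d) = Xβ + b_subject + ε`,  `b ~ N(0, σ²_b)`, `ε ~ N(0, σ²_e)`

   fitted by REML (lme4/lmerTest), with study group (diagnosis ×
   dichotomised Nancy activity) and colon location as fixed factors.
   Group differences are back-transformed LSD contrasts: fold change
   `FC = exp(Δ)` with 95% CI `exp(Δ ± t·SE)` (Satterthwaite df), no
   multiplicity correction. The module also reports variance components,
   `ICC = σ²_b/(σ²_b + σ²_e)`, covariate-adjusted refits, Spearman
   blood–mucosa correlations and proximal-vs-distal Kruskal–Wallis tests.

Because whole-slide cohorts are not shippable, the package includes a
**synthetic-data module**: a Beer–Lambert renderer that plants nuclei
with known class and compartment in crypt-like tissue, and a cohort
generator that draws log-normal counts with subject random effects and
planted fold changes. Every pipeline stage is validated against this
ground truth.

## Worked example

```r
library(ielquant)

# a ground-truthed synthetic H-DAB tile
g <- generate_tissue_image(tissue_spec(seed = 7))
g$image
#> <calibrated_image> 'synthetic-7': 512 x 512 px at 0.5 um/px (0.256 x 0.256 mm)

st  <- separate_stains(g$image)
det <- filter_by_area(detect_nuclei(st))
nrow(det$table)   # 255 detections for 254 planted cells
#> [1] 255

# a synthetic cohort with the planted IBD pattern, and the mixed model
tab <- generate_cohort_counts(ibd_pattern_design(seed = 1))
sub <- subset(tab, stain == "TCRdelta" & compartment == "epithelium")
sub$denom <- sub$epithelial_cells / 100
fit <- fit_lmm(sub, fixed = ~ group + location, denom_col = "denom")
icc(fit)
#> [1] 0.431903
pairwise_contrasts(fit, "group",
  pairs = c("CD_inactive vs UC_inactive", "UC_active vs UC_inactive"))
#>                     contrast   fc ci_low ci_high       p
#> 1 CD_inactive vs UC_inactive 0.43   0.34    0.54 1.9e-11
#> 2   UC_active vs UC_inactive 0.26   0.21    0.33 6.0e-23
```

The two fold changes read: inactive Crohn's mucosa has fewer than half
the γδ IELs of inactive ulcerative colitis (the generator planted 0.5),
and active UC has lost roughly three quarters of its γδ IELs relative to
inactive UC (planted 0.3). The ICC says ~43% of the log-count variance
is between subjects, which is what justifies the random intercept.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on simulated data
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # tiles + ground truth + cohort.csv
Rscript analysis/02_quantify.R     # segment, detect, classify, tabulate
Rscript analysis/03_statistics.R   # fold-change tables, ICCs, covariates
```

## Layout

```
R/                  package code (generators, segmentation, cells,
                    quantification, statistics)
analysis/           numbered workflow drivers
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (model, parameters, design choices)
```
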