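---
title: "Quantifying CD3 and γδ T cells in colon mucosal compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CD3 and γδ T cells in colon mucosal compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ielquant)
```

## What the package computes

Colon mucosa has three zones that matter for T-cell immunology: the
epithelium (home of the intraepithelial lymphocytes, IELs), a narrow
subepithelial zone immediately beneath the basement membrane, and the
lamina propria. `ielquant` takes calibrated RGB images of
immunohistochemically stained sections (hematoxylin counterstain + DAB
chromogen, one antibody per section: CD3 or TCRδ), reconstructs those
three compartments, counts stained and unstained cells in each, and
compares patient groups with a linear mixed model on log-transformed
counts. Group effects are reported as back-transformed fold changes with
95% confidence intervals, the natural effect measure for log-normal count
data.

The pipeline's conventions mirror common digital-pathology practice:
nucleus detection on the hematoxylin channel, an inclusive 125–3,000 px²
nucleus area filter defined at a 0.225 µm/px reference pixel size, a
1.5 µm cell expansion, a three-class (positive / negative / artefact)
random-forest object classifier, a 5 µm morphological expansion defining
the subepithelial zone, IEL and subepithelial counts reported per 100
epithelial cells, and lamina propria counts per mm² of mucosa.

## Stain model

Stain separation assumes the Beer–Lambert law: transmitted intensity per
channel is $I = 255 \cdot 10^{-\mathrm{OD}}$, and the channel OD vector is a
non-negative linear combination of unit stain vectors. Deconvolution
computes $\mathrm{OD} = -\log_{10}(\max(I, 1)/255)$ (the floor of 1 avoids
$\log 0$ on saturated pixels) and applies the inverse of the stain matrix,
clamping negative concentrations to zero. The default vectors are the
standard published H-DAB pair — hematoxylin ≈ (0.65, 0.70, 0.29), DAB ≈
(0.27, 0.57, 0.78), normalised — and are a parameter, because real
staining batches drift; the residual third vector is the normalised cross
product. The synthetic renderer is the exact forward model of this
inverse, so at zero noise the round trip is limited only by 8-bit
quantisation (≈0.2% at nuclear OD levels; the test suite bounds it at 1%).

## Geometry and units

All geometry runs in physical units through the microns-per-pixel
calibration.

* **Tissue** is total OD above a background threshold (default 0.025 OD,
  chosen on synthetic tiles where unstained stroma carries a faint
  hematoxylin wash), hole-filled and despeckled.
* **Epithelium** comes from a seeded random-forest pixel classifier over
  local features (stain ODs, Gaussian-smoothed ODs and local SD at 1, 3
  and 6 µm scales). This deliberately replaces trained deep segmentation
  networks: the package's subject is the quantification that follows the
  mask, so any segmenter honouring the same contract (image in, boolean
  epithelium mask out, trainable from annotations, deterministic under a
  seed) is interchangeable, and a desk-scale classifier keeps the whole
  pipeline reproducible without shipped weights. GeoJSON polygon
  annotations can be rasterised directly as an alternative mask source
  (even-odd rule at pixel centers, half-open so adjacent polygons never
  double-count a pixel).
* **The subepithelial band** is the set difference between the Euclidean
  5 µm expansion of the epithelium and the epithelium itself, clipped to
  tissue. The expansion thresholds the real-valued distance transform at
  `distance_um / mpp` pixels — never rounding the radius first, so band
  width is unbiased across resolutions. The distance transform is exact
  Euclidean (verified pixel-for-pixel against a brute-force oracle), and
  the three labels partition the tissue raster by construction.
* Mask clean-up fills only holes smaller than a configurable area
  (default equal to the minimum component area). Unconditional hole
  filling is wrong here: stroma pockets enclosed between crypt profiles
  are genuine anatomy, and filling them silently corrupts both the
  epithelium mask and the band.

Where the 5 µm expansion would leave the biopsy (at a cut edge), it is
clipped to tissue: only mucosal cells are counted. Whether to clip or to
count over luminal space was genuinely open; clipping was chosen because
the denominator (mucosa area) is also tissue-clipped, keeping the
per-mm² measure internally consistent.

## Cell detection and classification

Candidate nuclei are local maxima of the Gaussian-smoothed (1 µm)
hematoxylin OD above a foreground threshold (0.35 OD), with a minimum
peak separation of 3 µm; regions grow from the peaks over the foreground
by seeded propagation on the OD landscape (a marker-based watershed).
This replaces a pretrained star-convex detector with a deterministic,
dependency-free equivalent. Two of its settings are calibration choices,
not equivalences: the published detector's `threshold 0.01` is a learned
probability, mapped here to a peak threshold on the max-normalised OD
map, and detection runs at native tile resolution with areas converted
to px² at the 0.225 µm reference scale rather than resampling the
raster (the area bounds then mean the same physical area everywhere:
125 px² ≡ 6.33 µm²).

The area filter keeps nuclei in the **inclusive** range
[125, 3000] px²-at-reference — excluding "above and below" the bounds
keeps the bounds themselves — with a 10⁻⁹ relative tolerance so that
float round-off in the µm²→px² conversion cannot flip a boundary case.

Cell boundaries are nuclei dilated 1.5 µm; where expansions collide,
pixels go to the nearest nucleus (Voronoi split, implemented as seeded
propagation with a flat landscape and a large spatial weight). Features
over nucleus and cell regions (mean/max DAB, mean hematoxylin, area,
eccentricity from second moments, solidity against the convex hull) feed
a seeded three-class random forest. Artefacts — in the synthetic data,
high-OD specks below the area filter and smears above it — are excluded
from every downstream count.

Compartment membership uses the nucleus centroid's label. A cell
straddling the basement membrane therefore gets exactly one compartment,
which is what makes the subtraction identities exact: counts in the
band equal counts in the expanded epithelium minus counts in the
epithelium, and the three compartments sum to the whole mucosa.

## The statistical model

For a count $y$ with denominator $d$ (epithelial cells / 100, or mm²),
the model is

$$\log\left(\frac{y + 0.5}{d}\right) = X\beta + b_{\text{subject}} + \varepsilon,
\qquad b \sim N(0, \sigma^2_b),\ \varepsilon \sim N(0, \sigma^2_e),$$

fitted by REML. Subjects contribute several biopsies, so the random
intercept absorbs between-subject correlation; the intraclass correlation
$\sigma^2_b / (\sigma^2_b + \sigma^2_e)$ is reported per analysis. Fixed
factors are the five-level study group (diagnosis crossed with the
dichotomised Nancy index: grades 0–1 inactive, 2–4 active) and colon
location; age, gender, disease duration and oral corticosteroid use enter
as fixed effects in separate refits, and a group × location interaction
is checked separately.

Numerical and design choices:

* **Natural log** is used; fold changes are base-invariant but variance
  components are reported in natural-log units.
* **Zero counts** get an offset of +0.5 before the log (configurable; +1
  is the conventional sensitivity alternative). Zeros do occur — the
  cohort generator plants γδ baselines low enough to produce them.
* **Inference**: Satterthwaite degrees of freedom on t-type contrasts.
  When the subject variance is estimated at the boundary ($\hat\sigma^2_b = 0$)
  the fit reduces exactly to OLS and the contrasts to
  least-significant-difference t-tests with pooled MSE — both identities
  are enforced by tests against closed-form oracles.
* **Post hoc** comparisons are LSD: unadjusted pairwise contrasts of
  estimated marginal means. No multiplicity correction is applied, by
  design; the null-calibration test verifies the per-contrast 5% level.
  Estimated marginal means (rather than observed group means) are
  contrasted so that location imbalance between groups does not leak into
  the group effects.
* Back-transformed group summaries are reported both as model-based
  geometric means with CIs and as sample medians, labelled — they answer
  different questions and coincide only under perfect log-normality.
* γδ/CD3 ratios are computed per biopsy from the normalised measures of
  parallel sections (raw-count ratios would conflate section areas), then
  modelled on the log scale like any other response.
* A singular fixed-effect design aborts with the aliased column named;
  non-convergence is flagged on the result, not silently ignored.

Rank-based pieces — Spearman correlation between blood and mucosal
γδ/CD3 ratios (mid-ranks for ties) and the tie-corrected Kruskal–Wallis
comparison of proximal versus distal counts in inactive mucosa — are
delegated to the standard R implementations and cross-checked in the
tests against brute-force rank formulas. The degenerate all-tied input
returns H = 0 (no evidence of any location difference) rather than the
0/0 the raw tie correction would produce.

## What the synthetic data emulates — and what it does not

The tissue generator renders sinusoidal crypt-like epithelium ribbons
inside a rounded biopsy blob, gives epithelium and stroma distinct faint
hematoxylin washes (0.15 / 0.05 OD), plants elliptical nuclei
(radius 2.2–3.6 µm, hematoxylin OD 0.8, DAB 0.6 on positives) with a
hard-core minimum separation, and renders through the exact Beer–Lambert
forward model with optional Gaussian OD noise. Ground truth records every
cell's center, area, class and compartment plus the exact masks. Tiles
are 512 × 512 px at 0.5 µm/px (≈0.26 × 0.26 mm, ≈250 cells) by default.

The cohort generator draws counts as
$\mathrm{round}(\exp(\mu + b + \varepsilon))$ with per-(subject, series)
random intercepts, so the statistics module's model is correctly
specified up to rounding. Baseline geometric means (CD3: 2.8 IELs and 3.5
subepithelial cells per 100 epithelial cells, 600/mm² in lamina propria;
γδ: 0.6, 0.8, 60) are of the order reported for normal colon mucosa;
they are simulation parameters, not measurements. Default group sizes
(33/30/25/28/22 subjects, two biopsies each), log-scale SDs
($\sigma_b = 0.3$, $\sigma_e = 0.4$, ICC ≈ 0.36), a 1.35× proximal
effect and a 0.7× oral-steroid multiplier on γδ counts complete the
study conditions, and `ibd_pattern_design()` plants the qualitative
compartment pattern of interest: fewer γδ IELs in inactive Crohn's than
inactive UC, γδ IEL collapse with activity in UC but not CD, CD3 rising
below the basement membrane with activity while intraepithelial CD3
stays flat.

Passing against this ground truth shows the pipeline's arithmetic,
geometry and inference are right under the stated generative model. It
does **not** show robustness to what real slides add: staining batch
variation and drifting stain vectors, out-of-focus regions, touching and
overlapping nuclei beyond the planted separation, ulceration and
granulation morphologies, lymphoid aggregates, weak-versus-background
CD3 staining, or section-orientation effects. Those failure modes need
annotated real tissue to assess.

## Problem sizes and determinism

Every stochastic component takes an explicit seed and is bit-reproducible
(generators restore the caller's RNG state). The test suite validates the
tile pipeline on 20 default tiles (~5,000 planted cells) for detection,
single held-out tiles for classification and segmentation, 500 seeded
cohort replicates for fold-change CI coverage (planted FC 2.0,
50 subjects/group), and 200 five-group null cohorts (2,000 LSD contrasts)
for type-I calibration; these sizes keep the full suite at a few minutes
on one CPU while leaving the Monte-Carlo bands (coverage 93–97%,
rejection 3.5–6.5%) comfortably wider than their standard errors.

## Known limitations

* Surface and crypt epithelium are not separated; sections lacking
  surface epithelium conflate the two IEL populations.
* The centroid rule assigns boundary-straddling cells to a single
  compartment; at 0.5 µm/px this moves ≲2% of band cells in either
  direction.
* The pixel segmenter is a stand-in for whatever segmenter a user trusts;
  its features are tuned to H-DAB texture, not H&E.
* Per-biopsy ratio modelling (ratio first, model second) was chosen over
  contrasting modelled stain means; with parallel sections of unequal
  quality the two can differ, and the choice is exposed for sensitivity
  analysis via the model-spec arguments.
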