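Package: ielquant
Title: Compartmental Quantification of CD3 and Gamma-Delta T Cells in Colon Mucosa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis and statistics pipeline for counting
    immunohistochemically stained T cells in colon mucosal compartments.
    Separates hematoxylin and DAB stains by colour deconvolution, segments
    the epithelium with a trainable pixel classifier, constructs a 5 micron
    subepithelial band by Euclidean expansion, detects and classifies cell
    nuclei, and reports intraepithelial counts per 100 epithelial cells and
    lamina propria densities per square millimetre. Group differences are
    estimated with random-intercept linear mixed models on log counts and
    reported as back-transformed fold changes with confidence intervals.
    A synthetic-data module generates ground-truthed stained-tissue tiles
    and cohort count tables so the whole pipeline is testable without
    whole-slide images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    lme4,
    lmerTest,
    emmeans,
    ranger,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    ggplot2,
    dplyr
Config/testthat/edition: 3
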