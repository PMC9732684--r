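#!/usr/bin/env Rscript
# 01 -- simulate the study inputs.
#
# Produces (a) ground-truthed H-DAB tissue tiles standing in for scanned
# biopsy sections, one pair of parallel sections (CD3 / TCRdelta) per
# synthetic biopsy, and (b) a cohort count table with the planted IBD
# compartment pattern (fewer gamma-delta IELs in inactive CD than inactive
# UC, gamma-delta IEL collapse with activity in UC only, CD3 rise below
# the basement membrane with activity). Everything is seeded; a manifest
# records file hashes for reproducibility.

suppressPackageStartupMessages(library(ielquant))

seed <- 20260922L
out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

n_biopsies <- 4          # tile pairs: 2 for training, 2 held out
stain_fraction <- list(  # positive fractions differ by stain, as in tissue
  CD3 = c(epithelium = 0.12, subepithelial = 0.30, lamina_propria = 0.35),
  TCRdelta = c(epithelium = 0.03, subepithelial = 0.06, lamina_propria = 0.08)
)

manifest <- list()
for (b in seq_len(n_biopsies)) {
  for (stain in STAINS) {
    spec <- tissue_spec(seed = seed + 10L * b + (stain == "TCRdelta"),
                        positive_fraction = stain_fraction[[stain]],
                        artefact_density = 50)
    g <- generate_tissue_image(spec)
    prefix <- sprintf("biopsy%02d_%s", b, stain)
    img_path <- file.path(out_dir, paste0(prefix, ".png"))
    write_calibrated_image(g$image, img_path)
    write_ground_truth(g$truth, out_dir, prefix)
    manifest[[prefix]] <- list(
      file = basename(img_path),
      md5 = unname(tools::md5sum(img_path)),
      planted_cells = nrow(g$truth$cells),
      planted_positive = sum(g$truth$cells$class == "positive")
    )
    cat(sprintf("%s: %3d cells (%2d positive)\n", prefix,
                nrow(g$truth$cells),
                sum(g$truth$cells$class == "positive")))
  }
}

design <- ibd_pattern_design(seed = seed)
cohort <- generate_cohort_counts(design)
write.csv(cohort, file.path("results", "cohort.csv"), row.names = FALSE)
cat(sprintf("cohort: %d measurement rows, %d subjects, %d biopsies\n",
            nrow(cohort), length(unique(cohort$subject_id)),
            length(unique(cohort$biopsy_id))))

manifest$cohort <- list(file = "cohort.csv",
                        md5 = unname(tools::md5sum("results/cohort.csv")),
                        rows = nrow(cohort), seed = seed)
jsonlite::write_json(manifest, file.path("results", "simulate_manifest.json"),
                     auto_unbox = TRUE, digits = NA)
cat("manifest written to results/simulate_manifest.json\n")
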