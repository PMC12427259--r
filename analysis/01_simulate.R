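#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Builds the default synthetic cohort: 122 lesions (90 PTC-like, 14 FTC-like,
# 18 MTC-like), two orthogonal views each, speckle on. Writes the cohort
# manifest and per-image ground truth under results/, plus PNG images/masks
# when --write-images is passed (they are large; the later stages regenerate
# the cohort from the seed instead of reading them back).

suppressPackageStartupMessages(library(thyroquant))

args <- commandArgs(trailingOnly = TRUE)
seed <- 20250901L
write_images <- "--write-images" %in% args
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(n_per_class = c(PTC = 90, FTC = 14, MTC = 18),
                          seed = seed, views_per_lesion = 2L)

manifest <- do.call(rbind, lapply(cohort, function(ph)
  data.frame(image_id = ph$image_id, lesion_id = ph$lesion_id,
             subtype = ph$subtype, plane = ph$frame$plane_label,
             true_aspect_ratio = ph$truth$aspect_ratio,
             true_echogenicity_ratio = ph$truth$echogenicity_ratio,
             n_micro = ph$truth$n_micro, n_macro = ph$truth$n_macro,
             peripheral_count = ph$truth$peripheral_count,
             anechoic_pct = ph$truth$anechoic_pct)))
write.csv(manifest, "results/simulated/manifest.csv", row.names = FALSE)
jsonlite::write_json(list(seed = seed, n_images = nrow(manifest)),
                     "results/simulated/provenance.json", auto_unbox = TRUE)

if (write_images) {
  for (ph in cohort) {
    png::writePNG(ph$frame$intensities,
                  file.path("results/simulated", paste0(ph$image_id, ".png")))
    png::writePNG(ph$mask$mask + 0,
                  file.path("results/simulated", paste0(ph$image_id, "_mask.png")))
  }
}

cat(sprintf("simulated %d images (%d lesions); subtype medians of true echogenicity:\n",
            nrow(manifest), length(unique(manifest$lesion_id))))
print(round(tapply(manifest$true_echogenicity_ratio, manifest$subtype, median), 3))
cat("manifest written to results/simulated/manifest.csv\n")
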