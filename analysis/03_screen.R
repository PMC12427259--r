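#!/usr/bin/env Rscript
# Stage 3 — statistical screen and collinearity pruning.
#
# Shapiro-Wilk normality per subtype, Kruskal-Wallis across the three
# subtypes per feature, Dunn-Sidak post hoc pairs where the global test is
# significant, then Pearson-correlation pruning (|r| > 0.9) prioritizing
# screen-significant features. Reads results/features.csv from stage 2.

suppressPackageStartupMessages(library(thyroquant))

features <- read_feature_table("results/features.csv")
screen <- feature_screen(features)
write.csv(screen, "results/screen.csv", row.names = FALSE)

prune <- correlation_prune(features[, intersect(feature_names(), names(features))],
                           threshold = 0.9,
                           significant = screen$feature[screen$significant])
jsonlite::write_json(list(retained = prune$retained, dropped = prune$dropped,
                          threshold = prune$threshold),
                     "results/prune.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("%d/%d features significant at alpha = 0.05\n",
            sum(screen$significant), nrow(screen)))
cat("post hoc cells are present only for globally significant features\n")
cat(sprintf("pruning retained %d features: %s\n", length(prune$retained),
            paste(prune$retained, collapse = ", ")))
if (nrow(prune$dropped))
  cat(sprintf("dropped %s (|r| > %.1f with %s)\n",
              paste(prune$dropped$feature, collapse = ", "), prune$threshold,
              paste(unique(prune$dropped$partner), collapse = ", ")))
cat("written: results/screen.csv, results/prune.json\n")
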