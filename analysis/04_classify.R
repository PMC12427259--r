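#!/usr/bin/env Rscript
# Stage 4 — random-forest subtype classification.
#
# Stratified 70/30 split of the feature table, 100-tree random forest on the
# pruned feature set, OOB permutation importance, and a reduced model on the
# top-10 features. Writes the report JSON and the importance ranking CSV.

suppressPackageStartupMessages(library(thyroquant))

features <- read_feature_table("results/features.csv")
prune <- jsonlite::read_json("results/prune.json", simplifyVector = TRUE)

wf <- reduced_model_workflow(features, features = prune$retained,
                             params = forest_params(n_trees = 100, seed = 7),
                             k = min(10, length(prune$retained)), seed = 7)

write.csv(wf$importance, "results/importance.csv", row.names = FALSE)
jsonlite::write_json(
  list(full = list(oob_accuracy_pct = wf$full$oob_accuracy_pct,
                   test_accuracy_pct = wf$full$test$accuracy_pct,
                   per_class = wf$full$test$per_class,
                   confusion_pct = as.data.frame(wf$full$test$confusion_pct)),
       reduced = list(oob_accuracy_pct = wf$reduced$oob_accuracy_pct,
                      test_accuracy_pct = wf$reduced$test$accuracy_pct,
                      per_class = wf$reduced$test$per_class,
                      confusion_pct = as.data.frame(wf$reduced$test$confusion_pct)),
       top_features = wf$top_features),
  "results/classification.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("full model:    %d features, OOB %.1f%%, held-out %.1f%%\n",
            nrow(wf$importance), wf$full$oob_accuracy_pct,
            wf$full$test$accuracy_pct))
cat(sprintf("reduced model: %d features, OOB %.1f%%, held-out %.1f%%\n",
            length(wf$top_features), wf$reduced$oob_accuracy_pct,
            wf$reduced$test$accuracy_pct))
cat("top features by OOB permutation delta error:\n")
print(head(wf$importance, 5), row.names = FALSE)
cat("written: results/importance.csv, results/classification.json\n")
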