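#' Pipeline configuration
#'
#' Bundles every stage's parameters for \code{\link{run_pipeline}}:
#' cohort design (lesions per subtype, views per lesion, templates, speckle),
#' optional mask refinement, feature extraction, the statistical screen and
#' collinearity pruning, and the classifier. One global seed fans out to
#' per-stage child seeds through a fixed documented derivation
#' (\code{\link{derive_seed}}), so any stage can be rerun in isolation.
#'
#' @param seed global pipeline seed.
#' @param n_per_class named lesions-per-subtype vector.
#' @param views_per_lesion images per lesion.
#' @param templates subtype templates.
#' @param speckle_model \code{"rayleigh"} or \code{"none"}.
#' @param refine_masks run the active-contour refinement on each phantom
#'   mask before extraction (default FALSE: phantom masks are ground truth).
#' @param refinement a \code{\link{refinement_params}}.
#' @param extraction a \code{\link{feature_config}}.
#' @param prune_threshold collinearity cut (default 0.9).
#' @param forest a \code{\link{forest_params}}.
#' @param k_reduced reduced-model feature count.
#' @param split_unit \code{"image"} or \code{"lesion"}.
#' @param out_dir output directory, or \code{NULL} to skip writing files.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L,
                            n_per_class = c(PTC = 90, FTC = 14, MTC = 18),
                            views_per_lesion = 1L,
                            templates = default_subtype_templates(),
                            speckle_model = "rayleigh",
                            refine_masks = FALSE,
                            refinement = refinement_params(),
                            extraction = feature_config(),
                            prune_threshold = 0.9,
                            forest = forest_params(),
                            k_reduced = 10,
                            split_unit = "image",
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Derive a per-stage child seed from the global seed
#'
#' Deterministic 32-bit-safe mixing of the global seed with the stage name,
#' so stages are decorrelated but individually reproducible.
#'
#' @param seed global seed.
#' @param stage stage name string.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587 + 1)
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> (optionally refine) -> extract -> screen -> prune -> classify,
#' all parameters and seeds taken from one \code{\link{pipeline_config}}.
#' When \code{out_dir} is set, writes the feature table (CSV), the screen
#' table (CSV), the prune report and the classification reports (JSON), each
#' with a provenance block (package version, global seed, stage seeds).
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{features}, \code{screen}, \code{prune},
#'   \code{classification} (full + reduced reports and importance ranking),
#'   \code{refinement} (per-image modification Dice when enabled) and
#'   \code{provenance}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(simulate = derive_seed(config$seed, "simulate"),
                classify = derive_seed(config$seed, "classify"))
  cohort <- generate_cohort(n_per_class = config$n_per_class,
                            templates = config$templates,
                            seed = seeds$simulate,
                            views_per_lesion = config$views_per_lesion,
                            speckle_model = config$speckle_model)
  refinement <- NULL
  if (config$refine_masks) {
    refinement <- data.frame(image_id = character(0),
                             modification_dice = numeric(0))
    for (i in seq_along(cohort)) {
      rr <- refine_mask(cohort[[i]]$frame, cohort[[i]]$mask, config$refinement)
      cohort[[i]]$mask <- rr$mask
      cohort[[i]]$reference <- NULL  # recompute the band around the new contour
      refinement <- rbind(refinement,
        data.frame(image_id = cohort[[i]]$image_id,
                   modification_dice = rr$modification_dice))
    }
  }
  features <- extract_cohort(cohort, config$extraction)
  screen <- feature_screen(features)
  prune <- correlation_prune(features[, intersect(feature_names(), names(features))],
                             threshold = config$prune_threshold,
                             significant = screen$feature[screen$significant])
  classification <- reduced_model_workflow(
    features, features = prune$retained, params = config$forest,
    k = min(config$k_reduced, length(prune$retained)),
    unit = config$split_unit, seed = seeds$classify)
  provenance <- list(package_version = as.character(utils::packageVersion("thyroquant")),
                     seed = config$seed, stage_seeds = seeds,
                     n_per_class = as.list(config$n_per_class),
                     views_per_lesion = config$views_per_lesion,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  result <- list(features = features, screen = screen, prune = prune,
                 classification = classification, refinement = refinement,
                 provenance = provenance)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(config$out_dir, "features.csv"))
    utils::write.csv(screen, file.path(config$out_dir, "screen.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(provenance = provenance,
           prune = list(retained = prune$retained, dropped = prune$dropped),
           full = serialize_report(classification$full),
           reduced = serialize_report(classification$reduced),
           importance = classification$importance),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

serialize_report <- function(rep) {
  list(oob_accuracy_pct = rep$oob_accuracy_pct,
       test_accuracy_pct = rep$test$accuracy_pct,
       per_class = rep$test$per_class,
       confusion_pct = as.data.frame(rep$test$confusion_pct))
}
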