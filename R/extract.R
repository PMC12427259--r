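#' Canonical feature names
#'
#' The 21 quantitative B-mode features, in canonical column order:
#' morphology (aspect ratio, perimeter-to-area), echogenicity and echotexture
#' (normalized mean/median echogenicity, global SD, local entropy mean/SD and
#' the four co-occurrence descriptors), margin assessment (contour-gradient
#' mean/SD, normal-profile local-contrast mean/SD, KL margin divergence) and
#' structure (micro/macro calcification densities, calcified area percent,
#' peripheral calcification count, cystic area percent).
#'
#' @return character vector of length 21.
#' @export
feature_names <- function() {
  c("aspect_ratio", "perimeter_to_area",
    "echo_mean", "echo_median", "echo_std",
    "entropy_mean", "entropy_std",
    "glcm_contrast", "glcm_correlation", "glcm_homogeneity", "glcm_energy",
    "gradient_mean", "gradient_std",
    "profile_mean", "profile_std", "kl_divergence",
    "micro_density", "macro_density", "calcified_area_pct",
    "peripheral_calc_count", "cystic_area_pct")
}

#' Feature-extraction configuration
#'
#' All tunable parameters of the extraction stage with their defaults:
#' intensity exclusions 0.2/0.85, local-entropy radius 0.7 mm over 64 levels,
#' 32-level GLCM with the four unit offsets, +/-0.5 mm profile window sampled
#' at 0.1 mm, 64 KL histogram bins, calcification/anechoic thresholds
#' 0.85/0.2 with a 0.01 mm2 coherence filter, peripheral ring depth 0.2 of
#' the equivalent radius, and the sub-pixel perimeter estimator.
#'
#' @param ... overrides of the defaults listed above.
#' @return list of class \code{feature_config}.
#' @export
feature_config <- function(...) {
  cfg <- list(exclusion_low = 0.2, exclusion_high = 0.85,
              entropy_radius_mm = 0.7, entropy_levels = 64,
              glcm_levels = 32,
              glcm_offsets = list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1)),
              profile_half_width_mm = 0.5, profile_step_mm = 0.1,
              kl_bins = 64,
              calc_threshold = 0.85, anechoic_threshold = 0.2,
              min_component_area_mm2 = 0.01,
              zone_depth_fraction = 0.2,
              perimeter_estimator = "subpixel",
              band_stats = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "feature_config")
}

#' Extract the full feature vector for one image
#'
#' Runs every feature family on a frame/mask pair. Margin features (gradient,
#' profile, KL) operate on the frame normalized by the reference-parenchyma
#' mean, echogenicity on the raw frame with intensity exclusions, and
#' structural thresholds on the raw frame, following the respective feature
#' definitions. When no reference mask is supplied the automatic 1-4 mm
#' parenchyma band is used.
#'
#' @param frame an \code{\link{us_frame}}.
#' @param lesion a \code{\link{lesion_mask}}.
#' @param reference optional reference-parenchyma mask.
#' @param config a \code{\link{feature_config}}.
#' @return one-row data.frame with the columns of \code{\link{feature_names}}
#'   (plus auxiliary band statistics when \code{config$band_stats}).
#' @export
extract_features <- function(frame, lesion, reference = NULL,
                             config = feature_config()) {
  sp <- .spacing(frame)
  if (is.null(reference))
    reference <- reference_band(lesion, sp, frame = frame)
  geom_ar <- aspect_ratio(lesion, sp)
  geom_pa <- perimeter_to_area(lesion, sp, estimator = config$perimeter_estimator)
  echo <- echogenicity_stats(frame, lesion, reference,
                             exclusion_low = config$exclusion_low,
                             exclusion_high = config$exclusion_high)
  ent <- local_entropy_features(frame, lesion,
                                radius_mm = config$entropy_radius_mm,
                                levels = config$entropy_levels)
  glcm <- glcm_features(frame, lesion, levels = config$glcm_levels,
                        offsets = config$glcm_offsets)
  # parenchyma-normalized frame for the margin features
  imgn <- .frame_matrix(frame) / echo$mu_thyroid
  fn <- structure(list(intensities = imgn,
                       spacing_y_mm = sp[["y"]], spacing_x_mm = sp[["x"]],
                       plane_label = frame$plane_label,
                       source_id = frame$source_id),
                  class = "us_frame")
  grad <- gradient_features(fn, lesion)
  prof <- profile_features(fn, lesion,
                           half_width_mm = config$profile_half_width_mm,
                           step_mm = config$profile_step_mm)
  kl <- kl_margin_divergence(fn, lesion, reference, bins = config$kl_bins,
                             band_stats = config$band_stats)
  calc <- detect_calcifications(frame, lesion,
                                threshold = config$calc_threshold,
                                min_area_mm2 = config$min_component_area_mm2,
                                depth_fraction = config$zone_depth_fraction)
  cyst <- anechoic_ratio(frame, lesion, threshold = config$anechoic_threshold,
                         min_area_mm2 = config$min_component_area_mm2)
  out <- data.frame(
    aspect_ratio = geom_ar$aspect_ratio,
    perimeter_to_area = geom_pa$perimeter_to_area,
    echo_mean = echo$echo_mean, echo_median = echo$echo_median,
    echo_std = echo$echo_std,
    entropy_mean = ent$entropy_mean, entropy_std = ent$entropy_std,
    glcm_contrast = glcm$glcm_contrast,
    glcm_correlation = glcm$glcm_correlation,
    glcm_homogeneity = glcm$glcm_homogeneity,
    glcm_energy = glcm$glcm_energy,
    gradient_mean = grad$gradient_mean, gradient_std = grad$gradient_std,
    profile_mean = prof$profile_mean, profile_std = prof$profile_std,
    kl_divergence = kl$kl_divergence,
    micro_density = calc$micro_density, macro_density = calc$macro_density,
    calcified_area_pct = calc$calcified_area_pct,
    peripheral_calc_count = calc$peripheral_count,
    cystic_area_pct = cyst$cystic_area_pct)
  if (config$band_stats) {
    out$band_mean <- kl$band_mean
    out$band_median <- kl$band_median
    out$band_std <- kl$band_std
    out$peripheral_calc_pixels <- calc$peripheral_pixel_count
  }
  out
}

#' Extract features for a whole phantom cohort
#'
#' Applies \code{\link{extract_features}} to every record of
#' \code{\link{generate_cohort}}. Per-image failures (for example a lesion
#' that is predominantly cystic) yield an all-NA feature row and a warning so
#' downstream stages can drop them explicitly.
#'
#' @param cohort list of phantom records.
#' @param config a \code{\link{feature_config}}.
#' @return data.frame with \code{image_id}, \code{lesion_id}, \code{subtype}
#'   and one column per feature.
#' @export
extract_cohort <- function(cohort, config = feature_config()) {
  rows <- lapply(cohort, function(ph) {
    feats <- tryCatch(
      extract_features(ph$frame, ph$mask, ph$reference, config),
      error = function(e) {
        warning("feature extraction failed for ", ph$image_id, ": ",
                conditionMessage(e), call. = FALSE)
        as.data.frame(as.list(stats::setNames(rep(NA_real_,
          length(feature_names())), feature_names())))
      })
    cbind(data.frame(image_id = ph$image_id, lesion_id = ph$lesion_id,
                     subtype = ph$subtype), feats)
  })
  do.call(rbind, rows)
}

#' Write a labelled feature table to CSV
#'
#' One row per image: \code{image_id}, \code{lesion_id}, \code{subtype} and
#' the feature columns. Values survive a write/read round trip to within
#' 1e-9.
#'
#' @param cases data.frame as from \code{\link{extract_cohort}}, or a list of
#'   such one-row data.frames sharing one schema.
#' @param path output CSV path.
#' @export
write_feature_table <- function(cases, path) {
  if (is.list(cases) && !is.data.frame(cases)) {
    if (!length(cases)) stop("empty case list")
    schema <- names(cases[[1]])
    if (!all(vapply(cases, function(x) identical(names(x), schema), logical(1))))
      stop("cases have mismatched feature schemas")
    cases <- do.call(rbind, cases)
  }
  if (!is.data.frame(cases) || !nrow(cases)) stop("empty case list")
  utils::write.csv(format(cases, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table written by \code{\link{write_feature_table}}
#' @param path CSV path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(names(df), feature_names())) df[[nm]] <- as.numeric(df[[nm]])
  df
}
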