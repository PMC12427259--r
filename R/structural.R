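#' Detect and classify calcifications inside a lesion
#'
#' Connected components (8-connectivity) of pixels brighter than
#' \code{threshold} inside the lesion are treated as calcification candidates;
#' components smaller than \code{min_area_mm2} are discarded as artifacts.
#' Each surviving component is measured (area in mm2; maximum dimension =
#' largest pairwise pixel-centre distance in mm, anisotropy-aware), classified
#' as micro (max dim <= \code{size_cut_mm}) or macro (> cut), and assigned to
#' the peripheral or central zone by majority of its area in the peripheral
#' ring of \code{\link{zone_partition}} (ties go to peripheral).
#'
#' Detection runs on the raw [0,1] frame, not the parenchyma-normalized one,
#' because the threshold is an absolute normalized-grayscale cut.
#'
#' @inheritParams echogenicity_stats
#' @param threshold intensity cut for candidate calcifications (default 0.85).
#' @param min_area_mm2 minimum component area kept (default 0.01 mm2).
#' @param size_cut_mm micro/macro maximum-dimension cut (default 1.5 mm).
#' @param depth_fraction forwarded to \code{\link{zone_partition}}.
#' @return list with \code{components} (data.frame: area_mm2, max_dim_mm,
#'   size_class, zone, centroid_r_mm, centroid_c_mm), the counts
#'   \code{n_micro}, \code{n_macro}, \code{peripheral_count},
#'   \code{central_count}, \code{peripheral_pixel_count} (supra-threshold
#'   pixels in the peripheral ring, an auxiliary variant), densities
#'   \code{micro_density}, \code{macro_density} (1/mm2),
#'   \code{calcified_area_pct} and \code{lesion_area_mm2}.
#' @export
detect_calcifications <- function(frame, lesion, threshold = 0.85,
                                  min_area_mm2 = 0.01, size_cut_mm = 1.5,
                                  depth_fraction = 0.2) {
  .check_congruent(frame, lesion)
  img <- .frame_matrix(frame)
  lm <- .mask_matrix(lesion)
  sp <- .spacing(frame)
  px_area <- sp[["y"]] * sp[["x"]]
  A_lesion <- sum(lm) * px_area
  zones <- zone_partition(lesion, sp, depth_fraction = depth_fraction)
  cand <- lm & img > threshold
  comps <- component_table(cand, sp, min_area_mm2, zones$peripheral)
  if (nrow(comps)) {
    comps$size_class <- ifelse(comps$max_dim_mm <= size_cut_mm, "micro", "macro")
    comps$zone <- ifelse(comps$peripheral_frac >= 0.5, "peripheral", "central")
  } else {
    comps$size_class <- character(0); comps$zone <- character(0)
  }
  n_micro <- sum(comps$size_class == "micro")
  n_macro <- sum(comps$size_class == "macro")
  list(components = comps[, setdiff(names(comps), "peripheral_frac")],
       n_micro = n_micro, n_macro = n_macro,
       peripheral_count = sum(comps$zone == "peripheral"),
       central_count = sum(comps$zone == "central"),
       peripheral_pixel_count = sum(cand & zones$peripheral),
       micro_density = n_micro / A_lesion,
       macro_density = n_macro / A_lesion,
       calcified_area_pct = 100 * sum(comps$area_mm2) / A_lesion,
       lesion_area_mm2 = A_lesion)
}

component_table <- function(cand, sp, min_area_mm2, peripheral) {
  px_area <- sp[["y"]] * sp[["x"]]
  empty <- data.frame(area_mm2 = numeric(0), max_dim_mm = numeric(0),
                      centroid_r_mm = numeric(0), centroid_c_mm = numeric(0),
                      peripheral_frac = numeric(0))
  if (!any(cand)) return(empty)
  lab <- label_components(cand, 8)
  n <- max(lab)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    area <- nrow(idx) * px_area
    if (area < min_area_mm2) next
    pts <- cbind(idx[, 1] * sp[["y"]], idx[, 2] * sp[["x"]])
    hull <- if (nrow(pts) > 3) pts[grDevices::chull(pts), , drop = FALSE] else pts
    md <- if (nrow(hull) == 1) 0 else max(stats::dist(hull))
    rows[[k]] <- data.frame(
      area_mm2 = area, max_dim_mm = md,
      centroid_r_mm = mean(pts[, 1]), centroid_c_mm = mean(pts[, 2]),
      peripheral_frac = mean(peripheral[idx]))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Partition a lesion into central core and peripheral ring
#'
#' The central region is the lesion eroded to depth \code{depth_fraction}
#' times the equivalent radius \eqn{\sqrt{A/\pi}} (in mm, so the ring
#' thickness scales with lesion size); the peripheral zone is the remainder.
#' The partition is exact: central and peripheral are disjoint and their
#' union is the lesion. A fixed erosion depth in mm can be requested instead
#' via \code{depth_mm}. If the erosion would empty the central region the
#' whole lesion is classed peripheral and a warning is emitted.
#'
#' @inheritParams aspect_ratio
#' @param depth_fraction ring depth as a fraction of the equivalent radius
#'   (default 0.2).
#' @param depth_mm optional fixed ring depth in mm (overrides
#'   \code{depth_fraction}).
#' @return list of logical matrices \code{central} and \code{peripheral}, and
#'   \code{depth_mm} actually used.
#' @export
zone_partition <- function(mask, spacing, depth_fraction = 0.2, depth_mm = NULL) {
  lm <- .mask_matrix(mask)
  A <- sum(lm) * spacing[["y"]] * spacing[["x"]]
  d_req <- if (!is.null(depth_mm)) depth_mm else depth_fraction * sqrt(A / pi)
  if (d_req <= 0)
    return(list(central = lm, peripheral = lm & FALSE, depth_mm = 0))
  d <- signed_contour_distance(lm, spacing, max_dist_mm = d_req + 1)
  central <- lm & (-d) >= d_req
  if (!sum(central)) {
    warning("erosion depth ", signif(d_req, 3),
            " mm empties the central zone; whole lesion classed peripheral")
    return(list(central = central, peripheral = lm, depth_mm = d_req))
  }
  list(central = central, peripheral = lm & !central, depth_mm = d_req)
}

#' Anechoic (cystic/necrotic) area ratio
#'
#' Contiguous regions (8-connectivity) darker than \code{threshold} inside
#' the lesion, with components below \code{min_area_mm2} removed so that only
#' spatially coherent structures are retained; the ratio is the retained area
#' as a percentage of the lesion area.
#'
#' @inheritParams detect_calcifications
#' @param threshold intensity cut for anechoic pixels (default 0.2).
#' @return list with \code{cystic_area_pct}, \code{anechoic_area_mm2},
#'   \code{n_regions} and \code{lesion_area_mm2}.
#' @export
anechoic_ratio <- function(frame, lesion, threshold = 0.2, min_area_mm2 = 0.01) {
  .check_congruent(frame, lesion)
  img <- .frame_matrix(frame)
  lm <- .mask_matrix(lesion)
  sp <- .spacing(frame)
  px_area <- sp[["y"]] * sp[["x"]]
  A_lesion <- sum(lm) * px_area
  cand <- lm & img < threshold
  area <- 0; nreg <- 0L
  if (any(cand)) {
    lab <- label_components(cand, 8)
    sizes <- tabulate(lab[lab > 0]) * px_area
    keep <- sizes >= min_area_mm2
    area <- sum(sizes[keep]); nreg <- sum(keep)
  }
  list(cystic_area_pct = 100 * area / A_lesion,
       anechoic_area_mm2 = area, n_regions = nreg,
       lesion_area_mm2 = A_lesion)
}
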