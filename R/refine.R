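#' Refinement parameters
#'
#' @param opening_radius_mm radius of the disc structuring element for the
#'   initial morphological opening (default 0.2 mm).
#' @param contour_internal_weight smoothness (curvature) weight; the integer
#'   part sets the number of binary median-filter passes per iteration.
#' @param contour_external_weight image-attachment weight; 0 disables the
#'   data term so only smoothing acts.
#' @param max_iterations iteration cap for the active contour (default 200).
#' @param convergence_tol mean boundary displacement (px per iteration) below
#'   which the contour is considered converged (default 0.05).
#' @return list of class \code{refinement_params}.
#' @export
refinement_params <- function(opening_radius_mm = 0.2,
                              contour_internal_weight = 1,
                              contour_external_weight = 1,
                              max_iterations = 200,
                              convergence_tol = 0.05) {
  stopifnot(opening_radius_mm >= 0, contour_internal_weight >= 0,
            contour_external_weight >= 0, max_iterations >= 0,
            convergence_tol > 0)
  structure(list(opening_radius_mm = opening_radius_mm,
                 contour_internal_weight = contour_internal_weight,
                 contour_external_weight = contour_external_weight,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "refinement_params")
}

#' Refine an initial lesion mask
#'
#' Two-stage semi-automatic refinement of a manual-style mask: (1)
#' morphological opening with a disc of \code{opening_radius_mm} removes
#' small satellite artifacts; (2) a morphological active contour evolves the
#' mask boundary for up to \code{max_iterations} iterations or until the mean
#' boundary displacement per iteration falls below \code{convergence_tol}.
#'
#' The contour model is a region/edge hybrid of the Chan-Vese family
#' implemented morphologically on the binary level-set: within a narrow band
#' around the current contour, pixels are reassigned to lesion or background
#' according to which side's local mean intensity they are closer to (the
#' external term, which attracts the contour to intensity steps at the lesion
#' boundary), followed by binary median filtering, whose fixed points are
#' curvature-minimizing contours (the internal smoothness term). The result
#' is reduced to its largest connected component with holes filled, so the
#' returned mask is always a single connected region.
#'
#' @param frame an \code{\link{us_frame}}.
#' @param initial initial \code{\link{lesion_mask}} (largest component is
#'   used if it has several).
#' @param params a \code{\link{refinement_params}} list.
#' @return list with the refined \code{mask} (a \code{lesion_mask}),
#'   \code{iterations} used, \code{converged} flag, and
#'   \code{modification_dice} — the Dice coefficient between the initial and
#'   refined masks, i.e. the extent of correction introduced by the
#'   algorithm, not an accuracy against ground truth.
#' @export
refine_mask <- function(frame, initial, params = refinement_params()) {
  .check_congruent(frame, initial)
  img <- .frame_matrix(frame)
  sp <- .spacing(frame)
  m0 <- largest_component(.mask_matrix(initial))
  m <- m0
  if (params$opening_radius_mm > 0) {
    kern <- disc_kernel_mm(params$opening_radius_mm, sp)
    m <- EBImage::opening(m + 0, kern) > 0.5
    if (!sum(m))
      stop("mask vanished under morphological opening with radius ",
           params$opening_radius_mm, " mm")
    m <- largest_component(m)
  }
  converged <- FALSE
  iter <- 0L
  band_kern <- matrix(1, 5, 5)
  smooth_passes <- floor(params$contour_internal_weight)
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    old <- m
    if (params$contour_external_weight > 0) {
      dil <- EBImage::dilate(m + 0, band_kern) > 0.5
      ero <- EBImage::erode(m + 0, band_kern) > 0.5
      band <- dil & !ero
      inside <- m & !band
      shell <- (EBImage::dilate(dil + 0, band_kern) > 0.5) & !dil
      c1 <- if (sum(inside)) mean(img[inside]) else mean(img[m])
      c2 <- if (sum(shell)) mean(img[shell]) else c1
      # act only when the regional step exceeds the texture noise in the
      # band; with no edge evidence the internal (smoothing) term alone runs
      noise <- stats::sd(img[band])
      if (is.finite(noise) && abs(c1 - c2) > 0.5 * noise) {
        reassign <- band & (abs(img - c1) < abs(img - c2))
        m <- (m & !band) | reassign
      }
    }
    if (smooth_passes > 0) {
      for (i in seq_len(smooth_passes))
        m <- EBImage::medianFilter(m + 0, 1) > 0.5
    }
    if (!sum(m)) { m <- old; break }
    m <- EBImage::fillHull(largest_component(m) + 0) > 0.5
    moved <- sum(xor(m, old))
    blen <- max(1L, nrow(boundary_pixels(old)))
    if (moved / blen < params$convergence_tol) { converged <- TRUE; break }
  }
  list(mask = lesion_mask(m),
       iterations = iter,
       converged = converged || params$max_iterations == 0L,
       modification_dice = dice_coefficient(m0, m))
}

#' Dice similarity coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; 1 for identical non-empty masks, 0 for
#' disjoint ones. Symmetric and bounded in [0, 1].
#'
#' @param a,b congruent \code{\link{lesion_mask}} objects or logical matrices.
#' @return numeric scalar in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  ma <- .mask_matrix(a); mb <- .mask_matrix(b)
  if (!all(dim(ma) == dim(mb))) stop("masks must have the same shape")
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0) stop("both masks are empty")
  2 * sum(ma & mb) / (sa + sb)
}
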