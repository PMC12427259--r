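# Margin sharpness and boundary separability features.
#
# All three descriptors operate on the frame *after* parenchyma
# normalization (division by the reference mean); extract_features() performs
# that normalization before calling them, and the functions themselves are
# normalization-agnostic.

# Contour points resampled at ~step_mm arc spacing, with outward unit normals
# estimated from the gradient of the Gaussian-smoothed (sigma = 1 px) binary
# mask, which is stable on staircase contours.
contour_points_normals <- function(mask, spacing, step_mm = NULL) {
  m <- .mask_matrix(mask)
  if (is.null(step_mm)) step_mm <- min(spacing)
  polys <- contour_polygons(m, spacing)
  poly <- polys[[which.max(vapply(polys, polygon_length, numeric(1)))]]
  pts <- densify_polygon(poly, step_mm)
  # arc-length resample to uniform spacing
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  n <- max(8L, floor(total / step_mm))
  s_target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  ri <- stats::approx(arc, pts[, 1], xout = s_target)$y
  ci <- stats::approx(arc, pts[, 2], xout = s_target)$y
  sm <- EBImage::filter2(m + 0, EBImage::makeBrush(7, "gaussian", sigma = 1),
                         boundary = 0)
  # central differences of the smoothed mask, in mm
  gr <- (rbind(sm[-1, , drop = FALSE], sm[nrow(sm), ]) -
         rbind(sm[1, ], sm[-nrow(sm), , drop = FALSE])) / (2 * spacing[["y"]])
  gc <- (cbind(sm[, -1, drop = FALSE], sm[, ncol(sm)]) -
         cbind(sm[, 1], sm[, -ncol(sm), drop = FALSE])) / (2 * spacing[["x"]])
  nr_ <- bilinear_mm(gr, ri, ci, spacing)
  nc_ <- bilinear_mm(gc, ri, ci, spacing)
  len <- sqrt(nr_^2 + nc_^2)
  ok <- !is.na(len) & len > 1e-9
  # smoothed mask decreases outward, so the outward normal is -gradient
  data.frame(r_mm = ri[ok], c_mm = ci[ok],
             n_r = -nr_[ok] / len[ok], n_c = -nc_[ok] / len[ok])
}

#' Contour-gradient margin sharpness
#'
#' Samples the image gradient magnitude (mm-true central differences with
#' per-axis spacing) at uniformly resampled contour points of the lesion and
#' returns its mean and population SD. Sharper margins produce larger
#' gradients; blurring the margin lowers both statistics.
#'
#' @param frame an \code{\link{us_frame}}; expected to be parenchyma
#'   normalized by the caller.
#' @param lesion a \code{\link{lesion_mask}}.
#' @return list with \code{gradient_mean} and \code{gradient_std} (1/mm).
#' @export
gradient_features <- function(frame, lesion) {
  .check_congruent(frame, lesion)
  img <- .frame_matrix(frame)
  lm <- .mask_matrix(lesion)
  sp <- .spacing(frame)
  if (!sum(lm & !(.mask_matrix(boundary_mask(lm)))))
    stop("degenerate mask: no interior pixels")
  gr <- (rbind(img[-1, , drop = FALSE], img[nrow(img), ]) -
         rbind(img[1, ], img[-nrow(img), , drop = FALSE])) / (2 * sp[["y"]])
  gc <- (cbind(img[, -1, drop = FALSE], img[, ncol(img)]) -
         cbind(img[, 1], img[, -ncol(img), drop = FALSE])) / (2 * sp[["x"]])
  gmag <- sqrt(gr^2 + gc^2)
  cp <- contour_points_normals(lm, sp)
  g <- bilinear_mm(gmag, cp$r_mm, cp$c_mm, sp)
  g <- g[!is.na(g)]
  if (!length(g)) stop("no contour points inside the image")
  list(gradient_mean = mean(g), gradient_std = sqrt(mean((g - mean(g))^2)))
}

boundary_mask <- function(mask) {
  bp <- boundary_pixels(mask)
  out <- matrix(FALSE, nrow(.mask_matrix(mask)), ncol(.mask_matrix(mask)))
  out[bp] <- TRUE
  out
}

#' Normal-profile local contrast along the lesion margin
#'
#' For each contour point a 1D intensity profile I(s) is sampled by bilinear
#' interpolation along the outward normal, s in \code{[-half_width_mm,
#' +half_width_mm]} (s = 0 on the contour, negative inside), at
#' \code{step_mm} increments. The local contrast is \code{max I - min I} over
#' the window; its mean and population SD over all contour points summarize
#' margin sharpness.
#'
#' @inheritParams gradient_features
#' @param half_width_mm half-width of the profile window (default 0.5 mm).
#' @param step_mm profile sampling step (default 0.1 mm).
#' @param max_outside_frac error if more than this fraction of contour points
#'   have profiles leaving the image (default 0.2).
#' @return list with \code{profile_mean}, \code{profile_std} and \code{M}
#'   (number of contour points used).
#' @export
profile_features <- function(frame, lesion, half_width_mm = 0.5, step_mm = 0.1,
                             max_outside_frac = 0.2) {
  .check_congruent(frame, lesion)
  img <- .frame_matrix(frame)
  sp <- .spacing(frame)
  cp <- contour_points_normals(.mask_matrix(lesion), sp)
  s <- seq(-half_width_mm, half_width_mm, by = step_mm)
  rr <- matrix(cp$r_mm, nrow(cp), length(s)) + outer(cp$n_r, s)
  cc <- matrix(cp$c_mm, nrow(cp), length(s)) + outer(cp$n_c, s)
  vals <- matrix(bilinear_mm(img, as.vector(rr), as.vector(cc), sp),
                 nrow(cp), length(s))
  outside <- apply(vals, 1, anyNA)
  if (mean(outside) > max_outside_frac)
    stop("lesion too close to the image border: ",
         round(100 * mean(outside)), "% of profile windows leave the image")
  v <- vals[!outside, , drop = FALSE]
  if (nrow(v) < 8) stop("fewer than 8 usable contour points")
  c_local <- apply(v, 1, max) - apply(v, 1, min)
  list(profile_mean = mean(c_local),
       profile_std = sqrt(mean((c_local - mean(c_local))^2)),
       M = nrow(v))
}

#' Kullback-Leibler divergence between two histograms
#'
#' \eqn{D_{KL}(P \| Q) = \sum_i P_i \log(P_i/Q_i)} in nats. Bins with
#' \eqn{P_i = 0} contribute nothing. When some bin has \eqn{Q_i = 0} but
#' \eqn{P_i > 0} the divergence is infinite; in that case (and only then)
#' \code{epsilon} is added to every Q bin and Q is renormalized, keeping the
#' estimate finite while leaving exactly representable cases untouched.
#'
#' @param p,q non-negative vectors of equal length (normalized internally).
#' @param epsilon smoothing mass added to Q bins when needed.
#' @return the divergence in nats (non-negative).
#' @export
kl_divergence <- function(p, q, epsilon = 1e-6) {
  if (length(p) != length(q)) stop("histograms must have equal length")
  p <- p / sum(p); q <- q / sum(q)
  if (any(q == 0 & p > 0)) {
    q <- q + epsilon
    q <- q / sum(q)
  }
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Margin-band vs. parenchyma KL separability
#'
#' Builds the margin band (all pixels within \code{half_width_mm} of the
#' lesion contour, inside and outside, total width 1 mm by default), histograms
#' its intensities and those of the reference parenchyma on shared fixed bin
#' edges spanning \code{[0, max]} of the pooled values, and returns
#' \eqn{D_{KL}(P_{band} \| Q_{reference})} in nats. High values indicate a
#' margin whose intensity statistics are well separated from normal
#' parenchyma (sharp, distinct border); low values indicate blurring into the
#' background.
#'
#' @inheritParams gradient_features
#' @param reference reference-parenchyma mask; \code{NULL} for the automatic
#'   1-4 mm outer band.
#' @param bins number of histogram bins (default 64).
#' @param half_width_mm band half-width on each side of the contour.
#' @param band_stats if \code{TRUE}, also return the band's mean/median/sd as
#'   auxiliary descriptive statistics.
#' @return list with \code{kl_divergence} and optionally \code{band_mean},
#'   \code{band_median}, \code{band_std}.
#' @export
kl_margin_divergence <- function(frame, lesion, reference = NULL, bins = 64,
                                 half_width_mm = 0.5, band_stats = FALSE) {
  .check_congruent(frame, lesion)
  img <- .frame_matrix(frame)
  lm <- .mask_matrix(lesion)
  sp <- .spacing(frame)
  rm_ <- if (is.null(reference)) reference_band(lesion, sp) else .mask_matrix(reference)
  if (!sum(rm_)) stop("empty reference region")
  d <- signed_contour_distance(lm, sp, max_dist_mm = half_width_mm + 1)
  band <- abs(d) <= half_width_mm
  if (!sum(band)) stop("empty margin band")
  pv <- img[band]; qv <- img[rm_]
  hi <- max(pv, qv, 1e-12)
  edges <- seq(0, hi, length.out = bins + 1L)
  cutv <- function(x) tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), bins), bins)
  # total-count-scaled epsilon keeps smoothing below histogram resolution
  kl <- kl_divergence(cutv(pv), cutv(qv), epsilon = 1 / (10 * length(qv)))
  out <- list(kl_divergence = kl)
  if (band_stats)
    out <- c(out, list(band_mean = mean(pv), band_median = stats::median(pv),
                       band_std = stats::sd(pv)))
  out
}
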