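#' Parenchyma-normalized echogenicity and global heterogeneity
#'
#' Lesion pixels brighter than \code{exclusion_high} (possible calcifications)
#' or darker than \code{exclusion_low} (possible cystic/fluid areas) are
#' excluded; on the surviving pixels the mean and median gray level are
#' normalized by the mean intensity of the reference parenchyma (computed
#' without exclusion), giving the normalized echogenicity ratios. The global
#' heterogeneity sigma is the population standard deviation (denominator N)
#' over the same surviving pixel set.
#'
#' @param frame an \code{\link{us_frame}}.
#' @param lesion a \code{\link{lesion_mask}}.
#' @param reference reference-parenchyma mask (logical matrix or
#'   \code{lesion_mask}), disjoint from the lesion; if \code{NULL} an
#'   automatic band 1-4 mm outside the lesion is used (see
#'   \code{\link{reference_band}}).
#' @param exclusion_low,exclusion_high intensity exclusion thresholds.
#' @param min_pixels minimum number of lesion pixels that must survive the
#'   exclusion (default 100).
#' @return list with \code{echo_mean}, \code{echo_median}, \code{echo_std},
#'   \code{mu_lesion}, \code{mu_thyroid} and \code{n_pixels}.
#' @export
echogenicity_stats <- function(frame, lesion, reference = NULL,
                               exclusion_low = 0.2, exclusion_high = 0.85,
                               min_pixels = 100) {
  .check_congruent(frame, lesion)
  img <- .frame_matrix(frame)
  lm <- .mask_matrix(lesion)
  rm_ <- if (is.null(reference)) reference_band(lesion, .spacing(frame))
         else .mask_matrix(reference)
  if (any(rm_ & lm)) stop("reference mask overlaps the lesion")
  if (!sum(rm_)) stop("reference region is empty")
  vals <- img[lm]
  keep <- vals >= exclusion_low & vals <= exclusion_high
  if (sum(keep) < min_pixels)
    stop("lesion predominantly calcified/cystic: only ", sum(keep),
         " pixels survive the intensity exclusion")
  v <- vals[keep]
  mu_thyroid <- mean(img[rm_])
  if (mu_thyroid <= 0) stop("reference parenchyma mean intensity is zero")
  mu <- mean(v)
  list(echo_mean = mu / mu_thyroid,
       echo_median = stats::median(v) / mu_thyroid,
       echo_std = sqrt(mean((v - mu)^2)),
       mu_lesion = mu, mu_thyroid = mu_thyroid, n_pixels = length(v))
}

#' Automatic reference-parenchyma band
#'
#' Proxy for "surrounding normal thyroid parenchyma" when no explicit
#' reference mask is available: all pixels lying 1 to 4 mm outside the lesion
#' contour, clipped to the image, with extreme intensities (> 0.85 or < 0.2)
#' removed when a frame is supplied.
#'
#' @param lesion a \code{\link{lesion_mask}}.
#' @param spacing named spacing vector in mm.
#' @param frame optional \code{\link{us_frame}} used to drop extreme pixels.
#' @param inner_mm,outer_mm band distance limits (defaults 1 and 4 mm).
#' @return logical matrix.
#' @export
reference_band <- function(lesion, spacing, frame = NULL,
                           inner_mm = 1, outer_mm = 4) {
  lm <- .mask_matrix(lesion)
  d <- signed_contour_distance(lm, spacing, max_dist_mm = outer_mm + 1)
  band <- !lm & d >= inner_mm & d <= outer_mm
  if (!is.null(frame)) {
    img <- .frame_matrix(frame)
    band <- band & img <= 0.85 & img >= 0.2
  }
  band
}

#' Local-entropy texture over the lesion
#'
#' For every lesion pixel, intensities are quantized to \code{levels} bins and
#' the Shannon entropy \eqn{E = -\sum_k p_k \log p_k} (natural log) of the
#' histogram inside a circular neighborhood of radius \code{radius_mm}
#' (elliptical in pixels when spacing is anisotropic, clipped at the image
#' border) is computed. Returns the mean and population SD of the per-pixel
#' entropy over the lesion.
#'
#' Implementation: one box-counting convolution per quantized level that
#' actually occurs, so cost scales with the number of occupied levels.
#'
#' @inheritParams echogenicity_stats
#' @param radius_mm neighborhood radius (default 0.7 mm).
#' @param levels number of quantized intensity levels (default 64).
#' @param return_map if \code{TRUE}, also return the full entropy map.
#' @return list with \code{entropy_mean}, \code{entropy_std} and optionally
#'   \code{map}.
#' @export
local_entropy_features <- function(frame, lesion, radius_mm = 0.7, levels = 64,
                                   return_map = FALSE) {
  .check_congruent(frame, lesion)
  img <- .frame_matrix(frame)
  lm <- .mask_matrix(lesion)
  sp <- .spacing(frame)
  if (radius_mm < max(sp)) stop("neighborhood radius smaller than one pixel")
  k <- disc_kernel_mm(radius_mm, sp)
  q <- quantize_levels(img, levels)
  counts_total <- EBImage::filter2(matrix(1, nrow(img), ncol(img)), k, boundary = 0)
  plogp <- matrix(0, nrow(img), ncol(img))
  for (lev in sort(unique(as.vector(q)))) {
    ck <- EBImage::filter2((q == lev) + 0, k, boundary = 0)
    p <- ck / counts_total
    pos <- p > 1e-12
    plogp[pos] <- plogp[pos] + p[pos] * log(p[pos])
  }
  emap <- pmax(-plogp, 0)
  e <- emap[lm]
  out <- list(entropy_mean = mean(e), entropy_std = sqrt(mean((e - mean(e))^2)))
  if (return_map) out$map <- emap
  out
}

#' Gray-level co-occurrence features inside a lesion
#'
#' Intensities are quantized to \code{levels} gray levels; for each offset
#' \code{(dr, dc)} (row/column pixel displacement) co-occurring pairs are
#' counted only where both pixels lie inside the lesion mask, accumulated
#' symmetrically and normalized to a joint distribution \eqn{P(i,j)}. The
#' four classic descriptors are returned, averaged over the offsets:
#' contrast \eqn{\sum (i-j)^2 P}, correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j)P/(\sigma_i\sigma_j)}, homogeneity
#' \eqn{\sum P/(1+|i-j|)} and energy \eqn{\sum P^2}.
#'
#' A constant region has undefined correlation (\eqn{\sigma_i = 0}); it is
#' returned as \code{NA} while the other three descriptors are still computed.
#'
#' @inheritParams echogenicity_stats
#' @param levels number of gray levels (default 32).
#' @param offsets list of integer \code{c(dr, dc)} displacements; default the
#'   four unit offsets at 0, 45, 90 and 135 degrees.
#' @return list with \code{glcm_contrast}, \code{glcm_correlation},
#'   \code{glcm_homogeneity}, \code{glcm_energy}.
#' @export
glcm_features <- function(frame, lesion, levels = 32,
                          offsets = list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))) {
  .check_congruent(frame, lesion)
  img <- .frame_matrix(frame)
  lm <- .mask_matrix(lesion)
  q <- quantize_levels(img, levels)
  feats <- vapply(offsets, function(off) {
    P <- glcm_matrix(q, lm, off[1], off[2], levels)
    glcm_descriptors(P)
  }, numeric(4))
  res <- rowMeans(feats)  # NA correlation propagates to the average
  list(glcm_contrast = res[1], glcm_correlation = res[2],
       glcm_homogeneity = res[3], glcm_energy = res[4])
}

# Symmetric normalized GLCM for one (dr, dc) offset; pairs restricted to the
# mask. Returns an L x L probability matrix.
glcm_matrix <- function(q, mask, dr, dc, levels) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- q[r1, c1]; b <- q[r1 + dr, c1 + dc]
  ok <- mask[r1, c1] & mask[r1 + dr, c1 + dc]
  if (!any(ok)) stop("no co-occurring pixel pairs inside the mask")
  idx <- (b[ok] - 1L) * levels + a[ok]
  counts <- tabulate(idx, nbins = levels * levels)
  P <- matrix(counts, levels, levels)
  P <- P + t(P)
  P / sum(P)
}

glcm_descriptors <- function(P) {
  L <- nrow(P)
  i <- matrix(rep(seq_len(L), times = L), L)
  j <- matrix(rep(seq_len(L), each = L), L)
  contrast <- sum((i - j)^2 * P)
  homogeneity <- sum(P / (1 + abs(i - j)))
  energy <- sum(P^2)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  si <- sqrt(sum((i - mu_i)^2 * P)); sj <- sqrt(sum((j - mu_j)^2 * P))
  correlation <- if (si < 1e-12 || sj < 1e-12) NA_real_ else
    sum((i - mu_i) * (j - mu_j) * P) / (si * sj)
  c(contrast, correlation, homogeneity, energy)
}
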