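# Independent oracles and small fixture builders used across the suite.

iso_spacing <- function(s = 0.1) c(y = s, x = s)

disk_mask <- function(n, cx, cy, r) {
  outer(seq_len(n), seq_len(n), function(i, j) sqrt((i - cy)^2 + (j - cx)^2)) <= r
}

frame_of <- function(mat, s = 0.1) us_frame(mat, s, s)

# Brute-force GLCM by explicit pair enumeration: count (i, j) pairs at the
# given offset with both pixels in the mask, symmetrize, normalize, and
# compute the four descriptors from first principles.
glcm_oracle <- function(q, mask, dr, dc, levels) {
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (!mask[r, c] || !mask[r2, c2]) next
    counts[q[r, c], q[r2, c2]] <- counts[q[r, c], q[r2, c2]] + 1
  }
  counts <- counts + t(counts)
  P <- counts / sum(counts)
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  si <- sqrt(sum((i - mu_i)^2 * P)); sj <- sqrt(sum((j - mu_j)^2 * P))
  list(contrast = sum((i - j)^2 * P),
       correlation = if (si == 0 || sj == 0) NA_real_ else
         sum((i - mu_i) * (j - mu_j) * P) / (si * sj),
       homogeneity = sum(P / (1 + abs(i - j))),
       energy = sum(P^2))
}

# Per-pixel local-entropy map by direct histogramming of the elliptical
# neighborhood (clipped to the image), natural log.
entropy_oracle <- function(img, radius_mm, levels, spacing) {
  q <- pmin(pmax(floor(img * levels) + 1L, 1L), levels)
  nr <- nrow(img); nc <- ncol(img)
  ry <- radius_mm / spacing[["y"]]; rx <- radius_mm / spacing[["x"]]
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- max(1, ceiling(r - ry)):min(nr, floor(r + ry))
    cs <- max(1, ceiling(c - rx)):min(nc, floor(c + rx))
    vals <- c()
    for (rr in rs) for (cc in cs)
      if (((rr - r) / ry)^2 + ((cc - c) / rx)^2 <= 1)
        vals <- c(vals, q[rr, cc])
    p <- table(vals) / length(vals)
    out[r, c] <- -sum(p * log(p))
  }
  out
}

# Speckle-free phantom helper with sensible test defaults.
quiet_phantom <- function(seed = 1, ratio = 0.5, amp = 0.1, blur = 0.1,
                          radius = 4, stretch = 1, calcs = list(),
                          anechoic = 0, shape = c(128L, 128L)) {
  generate_phantom(phantom_spec(
    image_shape = shape, echogenicity_ratio = ratio, lesion_radius_mm = radius,
    irregularity_amplitude = amp, margin_blur_mm = blur,
    aspect_stretch = stretch, calcifications = calcs,
    anechoic_fraction = anechoic, speckle_model = "none", seed = seed))
}

# Parenchyma-normalized frame of a phantom (what extract_features feeds the
# margin features).
normalized_frame <- function(ph) {
  mu <- mean(ph$frame$intensities[ph$reference])
  us_frame(pmin(ph$frame$intensities / mu, 1),
           ph$frame$spacing_y_mm, ph$frame$spacing_x_mm)
}

# Default well-separated cohort, built once and shared across test files.
.fixture_env <- new.env(parent = emptyenv())
default_cohort_features <- function() {
  if (is.null(.fixture_env$features)) {
    cohort <- generate_cohort(n_per_class = c(PTC = 90, FTC = 14, MTC = 18),
                              seed = 20240901, views_per_lesion = 1L)
    .fixture_env$features <- extract_cohort(cohort)
  }
  .fixture_env$features
}
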