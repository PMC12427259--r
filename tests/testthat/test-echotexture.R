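mk_env <- function(lesion_vals, ref_val = 0.6, n = 40) {
  # lesion block 11:30 x 11:30 filled with lesion_vals (recycled), reference
  # strip on the right filled with ref_val
  img <- matrix(ref_val, n, n)
  lm <- matrix(FALSE, n, n); lm[11:30, 11:30] <- TRUE
  img[lm] <- lesion_vals
  rmask <- matrix(FALSE, n, n); rmask[, 36:40] <- TRUE
  list(frame = frame_of(img), lesion = lesion_mask(lm), ref = rmask)
}

test_that("normalized echogenicity closed forms", {
  e <- mk_env(0.6, 0.6)
  s <- echogenicity_stats(e$frame, e$lesion, e$ref)
  expect_equal(s$echo_mean, 1.0); expect_equal(s$echo_median, 1.0)
  expect_equal(s$echo_std, 0.0)
  e2 <- mk_env(0.3, 0.6)
  expect_equal(echogenicity_stats(e2$frame, e2$lesion, e2$ref)$echo_mean, 0.5)
  # half 0.3 / half 0.5 against reference 0.4: mean ratio 1, population sd 0.1
  e3 <- mk_env(rep(c(0.3, 0.5), 200), 0.4)
  s3 <- echogenicity_stats(e3$frame, e3$lesion, e3$ref)
  expect_equal(s3$echo_mean, 1.0)
  expect_equal(s3$echo_std, 0.1)
})

test_that("intensity exclusions drop calcified/cystic pixels from the stats", {
  vals <- rep(0.4, 400)
  vals[1:40] <- 0.95   # bright spots above 0.85
  vals[41:60] <- 0.05  # dark spots below 0.2
  e <- mk_env(vals, 0.4)
  s <- echogenicity_stats(e$frame, e$lesion, e$ref)
  expect_equal(s$echo_mean, 1.0)        # survivors are all 0.4
  expect_equal(s$n_pixels, 340L)
  # a lesion that is almost entirely excluded must error
  e2 <- mk_env(c(rep(0.95, 350), rep(0.4, 50)), 0.4)
  expect_error(echogenicity_stats(e2$frame, e2$lesion, e2$ref), "calcified/cystic")
})

test_that("echogenicity ratios are gain-invariant when no pixel crosses a threshold", {
  set.seed(2)
  vals <- runif(400, 0.35, 0.55)
  e <- mk_env(vals, 0.5)
  s1 <- echogenicity_stats(e$frame, e$lesion, e$ref)
  gain <- 1.3  # keeps everything inside (0.2, 0.85)
  e2 <- list(frame = frame_of(e$frame$intensities * gain / 1.0),
             lesion = e$lesion, ref = e$ref)
  s2 <- echogenicity_stats(e2$frame, e2$lesion, e2$ref)
  expect_equal(s2$echo_mean, s1$echo_mean, tolerance = 1e-12)
  expect_equal(s2$echo_median, s1$echo_median, tolerance = 1e-12)
})

test_that("local entropy closed forms: constant, uniform and two-level textures", {
  e <- mk_env(0.5, 0.6)
  r <- local_entropy_features(e$frame, e$lesion, radius_mm = 0.3, levels = 8)
  expect_equal(r$entropy_mean, 0)
  # checkerboard: every interior neighborhood is half one level, half another
  img <- matrix(0.6, 40, 40)
  img[11:30, 11:30] <- ifelse((row(matrix(0, 20, 20)) +
                               col(matrix(0, 20, 20))) %% 2 == 0, 0.26, 0.76)
  lm <- matrix(FALSE, 40, 40); lm[14:27, 14:27] <- TRUE  # stay interior
  r2 <- local_entropy_features(frame_of(img), lesion_mask(lm),
                               radius_mm = 0.25, levels = 4, return_map = TRUE)
  # odd neighborhood pixel counts keep the split at 9/12 rather than exactly
  # half, so the per-pixel value sits just below log 2
  expect_equal(r2$entropy_mean, log(2), tolerance = 0.02)
  expect_equal(r2$entropy_std, 0, tolerance = 1e-6)
  want <- entropy_oracle(img, 0.25, 4L, iso_spacing())
  expect_lt(max(abs(r2$map[lm] - want[lm])), 1e-8)
})

test_that("entropy map equals the per-pixel histogram oracle on a 32x32 image", {
  set.seed(7)
  img <- matrix(runif(32 * 32), 32, 32)
  lm <- matrix(TRUE, 32, 32)
  got <- local_entropy_features(frame_of(img), lesion_mask(lm),
                                radius_mm = 0.35, levels = 16,
                                return_map = TRUE)$map
  want <- entropy_oracle(img, 0.35, 16L, iso_spacing())
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("GLCM matches the checkerboard closed form", {
  cb <- ifelse((row(matrix(0, 8, 8)) + col(matrix(0, 8, 8))) %% 2 == 0,
               0.249, 0.749)  # quantizes to two adjacent levels at L = 2
  g <- glcm_features(frame_of(cb), lesion_mask(matrix(TRUE, 8, 8)),
                     levels = 2, offsets = list(c(0, 1)))
  expect_equal(g$glcm_contrast, 1.0)
  expect_equal(g$glcm_correlation, -1.0)
  expect_equal(g$glcm_homogeneity, 0.5)
  expect_equal(g$glcm_energy, 0.5)
})

test_that("a constant region yields degenerate GLCM values with NA correlation", {
  g <- glcm_features(frame_of(matrix(0.5, 8, 8)),
                     lesion_mask(matrix(TRUE, 8, 8)), levels = 8)
  expect_equal(g$glcm_contrast, 0)
  expect_equal(g$glcm_homogeneity, 1)
  expect_equal(g$glcm_energy, 1)
  expect_true(is.na(g$glcm_correlation))
})

test_that("GLCM equals the brute-force pair enumeration oracle", {
  set.seed(9)
  for (rep in 1:6) {
    img <- matrix(runif(64), 8, 8)
    lm <- matrix(runif(64) > 0.2, 8, 8)
    if (sum(lm) < 4) next
    for (off in list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))) {
      got <- tryCatch(
        glcm_features(frame_of(img), lesion_mask(lm), levels = 4,
                      offsets = list(off)),
        error = function(e) NULL)
      if (is.null(got)) next  # no pairs inside mask at this offset
      q <- thyroquant:::quantize_levels(img, 4)
      want <- glcm_oracle(q, lm, off[1], off[2], 4L)
      expect_equal(got$glcm_contrast, want$contrast, tolerance = 1e-12)
      expect_equal(got$glcm_homogeneity, want$homogeneity, tolerance = 1e-12)
      expect_equal(got$glcm_energy, want$energy, tolerance = 1e-12)
      expect_equal(got$glcm_correlation, want$correlation, tolerance = 1e-10)
    }
  }
})

test_that("GLCM energy is bounded by 1 and attained only by a single cell", {
  set.seed(3)
  for (rep in 1:5) {
    img <- matrix(runif(64), 8, 8)
    g <- glcm_features(frame_of(img), lesion_mask(matrix(TRUE, 8, 8)), levels = 4)
    expect_lte(g$glcm_energy, 1)
    expect_gt(g$glcm_energy, 0)
  }
})
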