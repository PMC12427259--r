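test_that("a lesion with no bright pixels reports zero calcification", {
  ph <- quiet_phantom(seed = 1, ratio = 0.5)
  rep <- detect_calcifications(ph$frame, ph$mask)
  expect_equal(rep$n_micro + rep$n_macro, 0L)
  expect_equal(rep$calcified_area_pct, 0)
  expect_equal(nrow(rep$components), 0L)
})

test_that("densities and area ratio follow the pixel-count arithmetic", {
  ph <- quiet_phantom(seed = 9, radius = 4.5,
                      calcs = list(list(max_dim_mm = 1.0, zone = "central"),
                                   list(max_dim_mm = 1.0, zone = "peripheral"),
                                   list(max_dim_mm = 2.0, zone = "central")))
  rep <- detect_calcifications(ph$frame, ph$mask)
  expect_equal(rep$n_micro, 2L); expect_equal(rep$n_macro, 1L)
  # identities rather than constants: D = N / A and R = 100 * sum(area) / A
  expect_equal(rep$micro_density, rep$n_micro / rep$lesion_area_mm2)
  expect_equal(rep$macro_density, rep$n_macro / rep$lesion_area_mm2)
  expect_equal(rep$calcified_area_pct,
               100 * sum(rep$components$area_mm2) / rep$lesion_area_mm2)
  # oracle: count supra-threshold pixels per drawn class directly
  bright <- ph$frame$intensities > 0.85 & ph$mask$mask
  expect_equal(sum(rep$components$area_mm2), sum(bright) * 0.01)
  # micro/macro split agrees with the drawn maximum dimensions
  expect_true(all(rep$components$max_dim_mm[rep$components$size_class == "macro"] > 1.5))
})

test_that("sub-minimum components are discarded as artifacts", {
  ph <- quiet_phantom(seed = 2, ratio = 0.5)
  img <- ph$frame$intensities
  idx <- which(ph$mask$mask, arr.ind = TRUE)
  centre <- idx[which.max(-abs(idx[, 1] - 64) - abs(idx[, 2] - 64)), ]
  img[centre[1], centre[2]] <- 0.99   # single-pixel speck = 0.01 mm2
  fr <- frame_of(img)
  rep <- detect_calcifications(fr, ph$mask, min_area_mm2 = 0.02)
  expect_equal(rep$n_micro + rep$n_macro, 0L)
  rep2 <- detect_calcifications(fr, ph$mask, min_area_mm2 = 0.005)
  expect_equal(rep2$n_micro, 1L)
})

test_that("zone partition is exact and matches the distance-transform oracle", {
  d <- disk_mask(121, 61, 61, 50)  # disk radius 5 mm
  z <- zone_partition(d, iso_spacing(), depth_fraction = 0.2)
  expect_true(!any(z$central & z$peripheral))
  expect_identical(z$central | z$peripheral, d)
  expect_equal(z$depth_mm, 0.2 * sqrt(sum(d) * 0.01 / pi), tolerance = 1e-12)
  # oracle: central pixels are those at least depth_mm from the boundary
  rho <- sqrt(outer(1:121, 1:121, function(i, j) (i - 61)^2 + (j - 61)^2)) * 0.1
  inner <- d & rho <= (5 - z$depth_mm)
  expect_gt(dice_coefficient(z$central, inner), 0.985)
})

test_that("zone partition edge cases: zero depth and vanishing centre", {
  d <- disk_mask(41, 21, 21, 15)
  z0 <- zone_partition(d, iso_spacing(), depth_fraction = 0)
  expect_identical(z0$central, d)
  expect_equal(sum(z0$peripheral), 0L)
  tiny <- disk_mask(41, 21, 21, 2)
  expect_warning(zt <- zone_partition(tiny, iso_spacing(), depth_mm = 1),
                 "peripheral")
  expect_identical(zt$peripheral, tiny)
})

test_that("anechoic ratio follows pixel-count arithmetic and coherence filtering", {
  ph <- quiet_phantom(seed = 12, ratio = 0.6, anechoic = 0.10)
  an <- anechoic_ratio(ph$frame, ph$mask)
  dark <- ph$frame$intensities < 0.2 & ph$mask$mask
  expect_equal(an$cystic_area_pct, 100 * sum(dark) / sum(ph$mask$mask))
  expect_equal(an$n_regions, 1L)
  # bright lesion: zero
  ph2 <- quiet_phantom(seed = 3, ratio = 0.9)
  expect_equal(anechoic_ratio(ph2$frame, ph2$mask)$cystic_area_pct, 0)
  # scattered single dark pixels fall below the coherence filter
  img <- ph2$frame$intensities
  idx <- which(ph2$mask$mask, arr.ind = TRUE)
  pick <- idx[seq(1, nrow(idx), by = 97), , drop = FALSE]
  img[pick] <- 0.05
  expect_equal(anechoic_ratio(frame_of(img), ph2$mask,
                              min_area_mm2 = 0.02)$cystic_area_pct, 0)
})

test_that("counts are spacing-invariant while densities rescale", {
  ph <- quiet_phantom(seed = 9, radius = 4.5,
                      calcs = list(list(max_dim_mm = 1.0, zone = "central")))
  r1 <- detect_calcifications(ph$frame, ph$mask)
  f2 <- us_frame(ph$frame$intensities, 0.2, 0.2)   # same raster, 2x spacing
  r2 <- detect_calcifications(f2, ph$mask, size_cut_mm = 3.0)
  expect_equal(r2$n_micro + r2$n_macro, r1$n_micro + r1$n_macro)
  expect_equal(r2$micro_density + r2$macro_density,
               (r1$micro_density + r1$macro_density) / 4, tolerance = 1e-12)
})
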