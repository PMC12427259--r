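test_that("gradient features vanish when the lesion is invisible", {
  ph <- quiet_phantom(seed = 3, ratio = 1.0, amp = 0, blur = 0)
  g <- gradient_features(ph$frame, ph$mask)
  expect_lt(g$gradient_mean, 1e-9)
})

test_that("gradient magnitude scales linearly with step height", {
  mk <- function(h) {
    ph <- quiet_phantom(seed = 4, ratio = 1 - h, amp = 0, blur = 0.1)
    gradient_features(ph$frame, ph$mask)$gradient_mean
  }
  g1 <- mk(0.2); g2 <- mk(0.4)
  expect_equal(g2 / g1, 2, tolerance = 0.02)
})

test_that("profile contrast closed forms on constant and step images", {
  ph <- quiet_phantom(seed = 5, ratio = 1.0, amp = 0, blur = 0)
  p0 <- profile_features(ph$frame, ph$mask)
  expect_equal(p0$profile_mean, 0)
  expect_equal(p0$profile_std, 0)
  # sharp radial step 0.2 inside / 0.8 outside: every window spans the step
  n <- 121
  d <- sqrt(outer(1:n, 1:n, function(i, j) (i - 61)^2 + (j - 61)^2)) * 0.1
  img <- ifelse(d <= 4, 0.2, 0.8)
  lm <- lesion_mask(d <= 4)
  p <- profile_features(frame_of(img), lm)
  expect_equal(p$profile_mean, 0.6, tolerance = 0.01)
  expect_lt(p$profile_std, 0.02)
})

test_that("profile contrast matches the Gaussian-smoothed step closed form", {
  # radial profile built directly from the normal CDF: I = 0.3 + 0.4 Phi((rho-R)/sigma)
  n <- 161; R <- 4
  rho <- sqrt(outer(1:n, 1:n, function(i, j) (i - 81)^2 + (j - 81)^2)) * 0.1
  for (sigma in c(0.2, 0.4)) {
    img <- 0.3 + 0.4 * stats::pnorm((rho - R) / sigma)
    lm <- lesion_mask(rho <= R)
    got <- profile_features(frame_of(img), lm)$profile_mean
    want <- 0.4 * (stats::pnorm(0.5 / sigma) - stats::pnorm(-0.5 / sigma))
    expect_equal(got, want, tolerance = 0.03)
    expect_lt(got, 0.4)  # blur wider than the window caps the contrast
  }
})

test_that("profiles near the image border trigger the coverage error", {
  n <- 61
  d <- sqrt(outer(1:n, 1:n, function(i, j) (i - 4)^2 + (j - 31)^2)) * 0.1
  img <- ifelse(d <= 3, 0.3, 0.6)
  expect_error(profile_features(frame_of(img), lesion_mask(d <= 3)),
               "border")
})

test_that("KL divergence closed forms and non-negativity", {
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  set.seed(11)
  for (i in 1:20) {
    p <- runif(8); q <- runif(8)
    expect_gte(kl_divergence(p, q), 0)
  }
  # smoothing keeps P-mass on empty Q bins finite
  expect_true(is.finite(kl_divergence(c(0.5, 0.5), c(1, 0))))
  expect_error(kl_divergence(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("margin KL is near zero when band and reference share one texture", {
  set.seed(13)
  ph <- generate_phantom(phantom_spec(echogenicity_ratio = 1.0,
    irregularity_amplitude = 0, margin_blur_mm = 0, speckle_model = "rayleigh",
    seed = 21))
  kl <- kl_margin_divergence(ph$frame, ph$mask, ph$reference)$kl_divergence
  # the floor is set by finite-sample bias with spatially correlated speckle
  # (roughly bins / (2 x effective sample count)), well below any real contrast
  expect_lt(kl, 0.15)
  ph2 <- generate_phantom(phantom_spec(echogenicity_ratio = 0.5,
    irregularity_amplitude = 0, margin_blur_mm = 0, speckle_model = "rayleigh",
    seed = 21))
  kl2 <- kl_margin_divergence(ph2$frame, ph2$mask, ph2$reference)$kl_divergence
  expect_gt(kl2, 10 * kl)
})

test_that("margin KL grows with lesion/parenchyma contrast", {
  kls <- vapply(c(0.95, 0.8, 0.65, 0.5, 0.35), function(r) {
    ph <- generate_phantom(phantom_spec(echogenicity_ratio = r,
      irregularity_amplitude = 0.1, margin_blur_mm = 0.15,
      speckle_model = "rayleigh", seed = 17))
    fn <- normalized_frame(ph)
    kl_margin_divergence(fn, ph$mask, ph$reference)$kl_divergence
  }, numeric(1))
  expect_true(all(diff(kls) > 0))
})

test_that("profile sampling agrees with a 10x finer rasterization", {
  ph <- quiet_phantom(seed = 6, ratio = 0.5, amp = 0.08, blur = 0.25)
  fn <- normalized_frame(ph)
  coarse <- profile_features(fn, ph$mask, step_mm = 0.1)$profile_mean
  fine <- profile_features(fn, ph$mask, step_mm = 0.01)$profile_mean
  expect_lt(abs(coarse / fine - 1), 0.01)
})
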