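test_that("Kruskal-Wallis closed form and degenerate cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)  # rank sums 6, 15, 24 in the standard H formula
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE))
  same <- kruskal_wallis(list(rep(2, 5), rep(2, 5)))
  expect_equal(same$H, 0); expect_equal(same$p, 1)
  expect_true(same$degenerate)
  expect_error(kruskal_wallis(list(1)), "two groups")
})

test_that("Kruskal-Wallis p agrees with a permutation oracle on small samples", {
  set.seed(5)
  x <- list(rnorm(8), rnorm(8, 0.8), rnorm(8))
  kw <- kruskal_wallis(x)
  pooled <- unlist(x); g <- rep(1:3, each = 8)
  perm_h <- replicate(4000, {
    gp <- sample(g)
    kruskal_wallis(split(pooled, gp))$H
  })
  p_perm <- mean(perm_h >= kw$H - 1e-12)
  expect_lt(abs(p_perm - kw$p), 0.03)
})

test_that("Kruskal-Wallis null p-values are uniform", {
  set.seed(17)
  ps <- replicate(2000, kruskal_wallis(split(rnorm(24), rep(1:3, 8)))$p)
  # H has a discrete support at n = 8 per group, so ignore the ties warning
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Dunn-Sidak closed forms and adjustment properties", {
  # Sidak step alone: 1 - (1 - 0.02)^3
  x <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(10, 11, 12, 13))
  ds <- dunn_sidak(x, c("a", "b"), m = 3)
  expect_equal(ds$p_adj, 1 - (1 - ds$p_raw)^3)
  expect_gte(ds$p_adj, ds$p_raw)
  expect_equal(dunn_sidak(x, c("a", "b"), m = 1)$p_adj,
               dunn_sidak(x, c("a", "b"), m = 1)$p_raw)
  # the closed form at p_raw = 0.02
  expect_equal(1 - (1 - 0.02)^3, 0.058808)
  expect_error(dunn_sidak(list(a = 1:3, b = numeric(0)), c("a", "b")), "empty")
})

test_that("Dunn z matches the tie-corrected pooled-rank formula by hand", {
  x <- list(g1 = c(1, 2, 2, 3), g2 = c(2, 4, 5, 6), g3 = c(7, 8, 8, 9))
  ds <- dunn_sidak(x, c("g1", "g2"), m = 3)
  rk <- rank(unlist(x)); N <- 12
  r1 <- mean(rk[1:4]); r2 <- mean(rk[5:8])
  ties <- table(unlist(x)); Tcorr <- sum(ties^3 - ties)
  v <- (N * (N + 1) / 12 - Tcorr / (12 * (N - 1))) * (1 / 4 + 1 / 4)
  expect_equal(ds$z, (r1 - r2) / sqrt(v), tolerance = 1e-12)
})

test_that("the shifted pair is flagged ahead of the unshifted pair", {
  set.seed(23)
  hits <- replicate(300, {
    x <- list(a = rnorm(12), b = rnorm(12), c = rnorm(12, 1.5))
    dunn_sidak(x, c("a", "c"))$p_adj < dunn_sidak(x, c("a", "b"))$p_adj
  })
  expect_gte(mean(hits), 0.95)
})

test_that("normality screen flags skew and respects its type-I rate", {
  set.seed(29)
  skew_hits <- replicate(200, normality_screen(list(rlnorm(50, sdlog = 1)))[1] < 0.05)
  expect_gte(mean(skew_hits), 0.9)
  null_hits <- replicate(500, normality_screen(list(rnorm(50)))[1] < 0.05)
  expect_lt(abs(mean(null_hits) - 0.05), 0.035)
  expect_warning(p <- normality_screen(list(rep(1, 10))), "constant|n < 3")
  expect_true(is.na(p[1]))
})

test_that("correlation pruning retains one of each collinear pair by priority", {
  set.seed(31)
  n <- 80
  base <- rnorm(n)
  tab <- data.frame(echo_mean = base,
                    echo_median = base + rnorm(n, sd = 0.01),  # r ~ 1
                    glcm_energy = 0.6 * base + rnorm(n, sd = 0.25),
                    aspect_ratio = rnorm(n),
                    entropy_mean = rnorm(n))
  pr <- correlation_prune(tab, threshold = 0.9)
  expect_true(xor("echo_mean" %in% pr$retained, "echo_median" %in% pr$retained))
  expect_true(all(c("aspect_ratio", "entropy_mean") %in% pr$retained))
  cm <- pr$matrix[pr$retained, pr$retained]
  expect_true(all(abs(cm[upper.tri(cm)]) <= 0.9))
  expect_true(all(pr$dropped$partner %in% pr$retained))
  # a significant member of a collinear pair wins retention
  pr2 <- correlation_prune(tab, threshold = 0.9, significant = "echo_median")
  expect_true("echo_median" %in% pr2$retained)
  expect_false("echo_mean" %in% pr2$retained)
})

test_that("constant columns are excluded with a warning before pruning", {
  tab <- data.frame(a = rnorm(20), b = rnorm(20), flat = rep(1, 20))
  expect_warning(pr <- correlation_prune(tab), "flat")
  expect_false("flat" %in% pr$retained)
})

test_that("screen gates post hoc cells on the global test", {
  set.seed(37)
  n <- 30
  tab <- data.frame(
    subtype = rep(c("PTC", "FTC", "MTC"), each = n),
    echo_mean = c(rnorm(n, 0), rnorm(n, 2), rnorm(n, 4)),   # separated
    glcm_energy = rnorm(3 * n))                             # null
  sc <- feature_screen(tab, features = c("echo_mean", "glcm_energy"))
  sig <- sc[sc$feature == "echo_mean", ]
  nul <- sc[sc$feature == "glcm_energy", ]
  expect_true(sig$significant)
  expect_false(is.na(sig$p_PTC_FTC))
  expect_true(all(is.na(c(nul$p_PTC_FTC, nul$p_PTC_MTC, nul$p_MTC_FTC))))
  expect_gte(sig$p_PTC_FTC, 0)
  expect_lte(sig$p_PTC_FTC, 1)
})
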