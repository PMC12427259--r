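gaussian_cases <- function(n_per_class = 60, p_noise = 2, sep = 6, seed = 1) {
  # three well-separated Gaussian clusters plus pure-noise columns
  set.seed(seed)
  classes <- c("PTC", "FTC", "MTC")
  rows <- do.call(rbind, lapply(seq_along(classes), function(k) {
    f1 <- rnorm(n_per_class, sep * k, 1)
    f2 <- rnorm(n_per_class, -sep * k, 1)
    cbind(f1, f2)
  }))
  df <- data.frame(image_id = sprintf("im-%03d", seq_len(nrow(rows))),
                   lesion_id = sprintf("les-%03d", seq_len(nrow(rows))),
                   subtype = rep(classes, each = n_per_class),
                   sig1 = rows[, 1], sig2 = rows[, 2])
  for (j in seq_len(p_noise)) df[[paste0("noise", j)]] <- rnorm(nrow(df))
  df
}

test_that("stratified split reproduces the 171/73 arithmetic on 244 images", {
  cases <- cohort_design(c(PTC = 90, FTC = 14, MTC = 18), views_per_lesion = 2)
  expect_equal(nrow(cases), 244L)
  sp <- stratified_split(cases, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 171L)
  expect_equal(nrow(sp$test), 73L)
  # per-class allocation within one unit of 0.7 x class size
  tr <- table(sp$train$subtype); full <- table(cases$subtype)
  expect_true(all(abs(as.numeric(tr) - 0.7 * as.numeric(full)) <= 1))
})

test_that("splits are seed-deterministic with fixed per-class counts", {
  cases <- cohort_design(c(PTC = 20, FTC = 10, MTC = 10), 1)
  a <- stratified_split(cases, 0.7, seed = 5)
  b <- stratified_split(cases, 0.7, seed = 5)
  c <- stratified_split(cases, 0.7, seed = 6)
  expect_identical(a$train$image_id, b$train$image_id)
  expect_false(identical(a$train$image_id, c$train$image_id))
  expect_equal(table(a$train$subtype), table(c$train$subtype))
})

test_that("lesion-level splitting keeps paired views together", {
  cases <- cohort_design(c(PTC = 10, FTC = 6, MTC = 6), views_per_lesion = 2)
  sp <- stratified_split(cases, 0.7, seed = 3, unit = "lesion")
  expect_equal(length(intersect(sp$train$lesion_id, sp$test$lesion_id)), 0L)
})

test_that("training errors and resubstitution optimism behave as expected", {
  df <- gaussian_cases(20, sep = 2, seed = 2)
  expect_error(train_forest(df[, c("sig1", "sig2")], rep("PTC", nrow(df))),
               "single class")
  fit <- train_forest(df[, c("sig1", "sig2", "noise1")], df$subtype,
                      forest_params(seed = 7))
  resub <- mean(as.character(stats::predict(fit$model, df)) == df$subtype)
  expect_gte(resub, oob_predictions(fit)$accuracy)
})

test_that("well-separated clusters reach high held-out accuracy", {
  accs <- vapply(1:10, function(s) {
    df <- gaussian_cases(60, sep = 6, seed = s)
    sp <- stratified_split(df, 0.7, seed = s)
    fit <- train_forest(sp$train[, c("sig1", "sig2", "noise1", "noise2")],
                        sp$train$subtype, forest_params(seed = s))
    pred <- stats::predict(fit$model, sp$test)
    mean(as.character(pred) == sp$test$subtype)
  }, numeric(1))
  expect_gte(min(accs), 0.95)
})

test_that("shuffled labels reduce OOB accuracy to the majority-class share", {
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    df <- gaussian_cases(25, sep = 6, seed = s)
    y <- sample(df$subtype)
    fit <- train_forest(df[, c("sig1", "sig2")], y, forest_params(seed = s))
    oob_predictions(fit)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.10)
})

test_that("OOB permutation importance separates signal from noise", {
  ranks_first <- logical(20); noise_small <- logical(20)
  for (s in 1:20) {
    df <- gaussian_cases(30, sep = 5, seed = s)
    fit <- train_forest(df[, c("sig1", "noise1", "noise2")], df$subtype,
                        forest_params(seed = s))
    imp <- oob_permutation_importance(fit, seed = s)
    ranks_first[s] <- imp$feature[1] == "sig1"
    noise_small[s] <- all(abs(imp$delta_error[imp$feature != "sig1"]) < 0.06)
  }
  expect_gte(mean(ranks_first), 0.95)
  expect_gte(mean(noise_small), 0.9)
})

test_that("duplicating rows preserves the sign of informative importance", {
  df <- gaussian_cases(30, sep = 5, seed = 3)
  fit1 <- train_forest(df[, c("sig1", "noise1")], df$subtype, forest_params(seed = 3))
  df2 <- rbind(df, df)
  fit2 <- train_forest(df2[, c("sig1", "noise1")], df2$subtype, forest_params(seed = 3))
  i1 <- oob_permutation_importance(fit1, seed = 3)
  i2 <- oob_permutation_importance(fit2, seed = 3)
  expect_gt(i1$delta_error[i1$feature == "sig1"], 0)
  expect_gt(i2$delta_error[i2$feature == "sig1"], 0)
})

test_that("evaluation metrics follow their definitions", {
  perfect <- evaluate(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(perfect$accuracy_pct, 100)
  expect_true(all(perfect$per_class$f1_pct == 100))
  expect_equal(diag(perfect$confusion_pct), c(100, 100, 100),
               ignore_attr = TRUE)
  # all-A predictions on a 10/10 truth
  ev <- evaluate(rep("A", 20), rep(c("A", "B"), each = 10))
  pa <- ev$per_class[ev$per_class$class == "A", ]
  pb <- ev$per_class[ev$per_class$class == "B", ]
  expect_equal(pa$recall_pct, 100); expect_equal(pa$precision_pct, 50)
  expect_equal(pb$recall_pct, 0)
  # harmonic mean of 75.0 and 64.3
  ev2 <- list(p = 75.0, r = 64.3)
  expect_equal(2 * ev2$p * ev2$r / (ev2$p + ev2$r), 69.25, tolerance = 1e-3)
  # confusion rows sum to 100; accuracy = case-weighted mean recall
  set.seed(41)
  truth <- sample(c("A", "B", "C"), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(c("A", "B", "C"), 60, TRUE))
  ev3 <- evaluate(pred, truth)
  expect_equal(unname(rowSums(ev3$confusion_pct)), rep(100, nrow(ev3$confusion_pct)))
  w <- as.numeric(table(truth)[ev3$per_class$class])
  expect_equal(ev3$accuracy_pct,
               sum(ev3$per_class$recall_pct * w) / sum(w), tolerance = 1e-9)
  expect_warning(evaluate(c("A", "B"), c("A", "A")), "absent")
})

test_that("reduced workflow with k = p and matched seeds reproduces the full model", {
  df <- gaussian_cases(25, sep = 5, seed = 9)
  feats <- c("sig1", "sig2", "noise1", "noise2")
  wf <- reduced_model_workflow(df, features = feats, k = length(feats),
                               params = forest_params(seed = 11), seed = 4,
                               reduced_seed = 11)
  expect_equal(sort(wf$top_features), sort(feats))
  expect_equal(wf$reduced$test$accuracy_pct, wf$full$test$accuracy_pct)
  expect_equal(wf$reduced$oob_accuracy_pct, wf$full$oob_accuracy_pct)
})
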