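#' Random-forest parameters
#'
#' @param n_trees ensemble size (default 100).
#' @param predictors_per_split candidate predictors per node; \code{NULL} for
#'   the ceiling-square-root rule applied to the feature count at fit time.
#' @param seed RNG seed for bootstrap and split sampling.
#' @return list of class \code{forest_params}. Splits use the Gini impurity
#'   and each tree is grown on a bootstrap sample (the backend's defaults).
#' @export
forest_params <- function(n_trees = 100, predictors_per_split = NULL, seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 predictors_per_split = predictors_per_split,
                 seed = as.integer(seed)),
            class = "forest_params")
}

#' Stratified train/test split
#'
#' Allocates round(fraction x class size) units of every class to training,
#' then adjusts by largest fractional remainder so the total equals
#' round(fraction x N). With \code{unit = "lesion"} the two orthogonal views
#' of a lesion always land on the same side of the split (avoiding the
#' information leak of paired views); \code{unit = "image"} splits images
#' independently.
#'
#' @param cases data.frame with \code{image_id}, \code{lesion_id},
#'   \code{subtype} columns.
#' @param train_fraction fraction allocated to training (default 0.7).
#' @param seed RNG seed.
#' @param unit \code{"image"} (default) or \code{"lesion"}.
#' @return list with data.frames \code{train} and \code{test}.
#' @export
stratified_split <- function(cases, train_fraction = 0.7, seed = 1L,
                             unit = c("image", "lesion")) {
  unit <- match.arg(unit)
  key <- if (unit == "image") cases$image_id else cases$lesion_id
  units <- unique(data.frame(key = key, subtype = cases$subtype))
  tab <- table(units$subtype)
  if (any(tab < 2)) stop("every class needs at least 2 units to split")
  exact <- train_fraction * as.numeric(tab)
  n_train <- round(exact)
  total_target <- round(train_fraction * nrow(units))
  while (sum(n_train) != total_target) {
    resid <- exact - n_train
    if (sum(n_train) < total_target) {
      i <- which.max(resid); n_train[i] <- n_train[i] + 1L
    } else {
      i <- which.min(resid); n_train[i] <- n_train[i] - 1L
    }
  }
  n_train <- pmin(pmax(n_train, 1L), as.numeric(tab) - 1L)
  with_seed(seed, {
    train_keys <- unlist(lapply(seq_along(tab), function(i) {
      k <- units$key[units$subtype == names(tab)[i]]
      sample(k, n_train[i])
    }))
    list(train = cases[key %in% train_keys, , drop = FALSE],
         test = cases[!key %in% train_keys, , drop = FALSE])
  })
}

#' Train a random forest for subtype classification
#'
#' Fits a bagged ensemble (Gini splits, bootstrap sampling, majority vote)
#' with \code{ceiling(sqrt(p))} candidate predictors per split by default,
#' recording the per-tree in-bag counts so that out-of-bag membership — the
#' basis of the OOB error and permutation importance — is available.
#'
#' @param x data.frame or matrix of predictors.
#' @param y factor (or character) of class labels.
#' @param params a \code{\link{forest_params}}.
#' @return list of class \code{subtype_forest} with the fitted backend model,
#'   the training data, per-tree OOB membership and the class prevalence
#'   used for vote tie-breaking.
#' @export
train_forest <- function(x, y, params = forest_params()) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("training set contains a single class")
  x <- as.data.frame(x)
  p <- ncol(x)
  mtry <- if (is.null(params$predictors_per_split)) ceiling(sqrt(p))
          else min(max(1L, params$predictors_per_split), p)
  rf <- with_seed(params$seed,
    randomForest::randomForest(x = x, y = y, ntree = params$n_trees,
                               mtry = mtry, keep.inbag = TRUE,
                               keep.forest = TRUE))
  structure(list(model = rf, x = x, y = y, params = params,
                 oob = rf$inbag == 0,
                 prevalence = table(y)),
            class = "subtype_forest")
}

# Per-tree class predictions (n x ntree character matrix).
tree_predictions <- function(fit, newx) {
  stats::predict(fit$model, newdata = as.data.frame(newx),
                 predict.all = TRUE)$individual
}

# Majority vote over selected trees; ties broken by larger training
# prevalence, then lexicographically.
majority_vote <- function(pred_mat, use, prevalence) {
  classes <- names(prevalence)
  pref <- order(-as.numeric(prevalence), classes)
  vapply(seq_len(nrow(pred_mat)), function(i) {
    p <- pred_mat[i, use[i, ]]
    if (!length(p)) return(NA_character_)
    tab <- table(factor(p, levels = classes))
    top <- which(tab == max(tab))
    classes[pref[pref %in% top][1]]
  }, character(1))
}

#' Out-of-bag predictions and error of a fitted forest
#'
#' For every training sample, the majority vote over only the trees whose
#' bootstrap sample excluded it. \code{x} may be a perturbed copy of the
#' training predictors (used by the permutation importance).
#'
#' @param fit a \code{\link{train_forest}} result.
#' @param x predictors congruent with the training set (default: the
#'   training predictors themselves).
#' @return list with \code{predictions}, \code{error} (fraction
#'   misclassified), \code{per_tree_error} (vector over trees) and
#'   \code{accuracy}.
#' @export
oob_predictions <- function(fit, x = fit$x) {
  pm <- tree_predictions(fit, x)
  votes <- majority_vote(pm, fit$oob, fit$prevalence)
  ok <- !is.na(votes)
  err <- mean(votes[ok] != as.character(fit$y)[ok])
  per_tree <- vapply(seq_len(ncol(pm)), function(t) {
    o <- fit$oob[, t]
    if (!any(o)) return(NA_real_)
    mean(pm[o, t] != as.character(fit$y)[o])
  }, numeric(1))
  list(predictions = votes, error = err, accuracy = 1 - err,
       per_tree_error = per_tree)
}

#' OOB permutation feature importance
#'
#' For each feature, its column is randomly permuted across the training
#' rows and, for every tree, the misclassification error on that tree's
#' out-of-bag samples is recomputed; the importance is the mean over trees of
#' the permuted-minus-baseline OOB error (the delta error). Features whose
#' permutation does not degrade OOB predictions score near zero (or
#' negative); the ranking is returned in descending importance.
#'
#' @param fit a \code{\link{train_forest}} result.
#' @param seed RNG seed for the permutations.
#' @return data.frame with \code{feature}, \code{delta_error} and
#'   \code{rank}, ordered by descending importance.
#' @export
oob_permutation_importance <- function(fit, seed = 1L) {
  base <- oob_predictions(fit)$per_tree_error
  feats <- colnames(fit$x)
  with_seed(seed, {
    delta <- vapply(feats, function(f) {
      xp <- fit$x
      xp[[f]] <- sample(xp[[f]])
      perm <- oob_predictions(fit, xp)$per_tree_error
      mean(perm - base, na.rm = TRUE)
    }, numeric(1))
    ord <- order(-delta)
    data.frame(feature = feats[ord], delta_error = unname(delta[ord]),
               rank = seq_along(feats))
  })
}

#' Classification report
#'
#' Per-class precision, recall and F1 in percent, overall accuracy, and the
#' row-normalized confusion matrix (true class on rows, rows summing to
#' 100 percent). Classes absent from the truth are omitted with a warning.
#'
#' @param predictions predicted labels.
#' @param truth true labels.
#' @return list with \code{per_class} (data.frame), \code{accuracy_pct} and
#'   \code{confusion_pct}.
#' @export
evaluate <- function(predictions, truth) {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  if (length(predictions) != length(truth)) stop("label sets differ in length")
  classes <- sort(unique(c(truth, predictions)))
  absent <- setdiff(classes, unique(truth))
  if (length(absent))
    warning("classes absent from truth omitted from per-class rows: ",
            paste(absent, collapse = ", "), call. = FALSE)
  rows_cls <- setdiff(classes, absent)
  per <- do.call(rbind, lapply(rows_cls, function(cl) {
    tp <- sum(predictions == cl & truth == cl)
    fp <- sum(predictions == cl & truth != cl)
    fn <- sum(predictions != cl & truth == cl)
    prec <- if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp)
    rec <- 100 * tp / (tp + fn)
    f1 <- if (is.na(prec) || prec + rec == 0) NA_real_ else
      2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision_pct = prec, recall_pct = rec,
               f1_pct = f1)
  }))
  conf <- matrix(0, length(rows_cls), length(classes),
                 dimnames = list(true = rows_cls, predicted = classes))
  for (cl in rows_cls) {
    n <- sum(truth == cl)
    for (pc in classes)
      conf[cl, pc] <- 100 * sum(truth == cl & predictions == pc) / n
  }
  list(per_class = per,
       accuracy_pct = 100 * mean(predictions == truth),
       confusion_pct = conf)
}

#' Full-plus-reduced random-forest workflow
#'
#' Trains the full-feature forest on a stratified split, evaluates it
#' out-of-bag and on the held-out test set, ranks features by OOB
#' permutation delta error, then retrains on the top \code{k} features with
#' the same split and a fresh seed and evaluates again.
#'
#' @param cases feature table with \code{image_id}, \code{lesion_id},
#'   \code{subtype} and feature columns.
#' @param features feature columns to use (default: canonical names present).
#' @param params a \code{\link{forest_params}}.
#' @param k reduced-model feature count (default 10).
#' @param train_fraction,unit forwarded to \code{\link{stratified_split}}.
#' @param seed split/permutation seed.
#' @param reduced_seed seed of the reduced refit; default \code{NULL} derives
#'   a fresh seed (\code{params$seed + 1}).
#' @return list with \code{full} and \code{reduced} reports (each containing
#'   \code{test} evaluation, \code{oob_accuracy_pct} and the fitted model),
#'   \code{importance}, \code{top_features} and the \code{split}.
#' @export
reduced_model_workflow <- function(cases, features = NULL,
                                   params = forest_params(), k = 10,
                                   train_fraction = 0.7,
                                   unit = "image", seed = 1L,
                                   reduced_seed = NULL) {
  if (is.null(features))
    features <- intersect(feature_names(), names(cases))
  if (k > length(features)) stop("k exceeds the number of features")
  complete <- stats::complete.cases(cases[, features, drop = FALSE])
  if (any(!complete))
    message("dropping ", sum(!complete), " case(s) with missing features")
  cases <- cases[complete, , drop = FALSE]
  split <- stratified_split(cases, train_fraction, seed = seed, unit = unit)
  fit_eval <- function(feat_set, fit_params) {
    fit <- train_forest(split$train[, feat_set, drop = FALSE],
                        split$train$subtype, fit_params)
    oob <- oob_predictions(fit)
    test_pred <- majority_vote(
      tree_predictions(fit, split$test[, feat_set, drop = FALSE]),
      matrix(TRUE, nrow(split$test), fit$params$n_trees), fit$prevalence)
    list(fit = fit, oob_accuracy_pct = 100 * oob$accuracy,
         test = evaluate(test_pred, split$test$subtype))
  }
  full <- fit_eval(features, params)
  importance <- oob_permutation_importance(full$fit, seed = seed)
  # keep the original column order so k = p reproduces the full design
  top <- features[features %in% importance$feature[seq_len(k)]]
  red_params <- params
  red_params$seed <- if (is.null(reduced_seed)) params$seed + 1L
                     else as.integer(reduced_seed)
  reduced <- fit_eval(top, red_params)
  list(full = full, reduced = reduced, importance = importance,
       top_features = top, split = split)
}
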