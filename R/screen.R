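#' Kruskal-Wallis test across subtype groups
#'
#' Rank-based H with tie correction and a chi-square reference distribution
#' on k - 1 degrees of freedom (delegated to \code{stats::kruskal.test}).
#' When every value is identical across all groups the statistic is
#' degenerate; H = 0 and p = 1 are returned with a \code{degenerate} flag.
#'
#' @param values list of numeric vectors, one per group (>= 2 groups, total
#'   N >= 3).
#' @return list with \code{H}, \code{p} and \code{degenerate}.
#' @export
kruskal_wallis <- function(values) {
  if (!is.list(values) || length(values) < 2)
    stop("values must be a list of at least two groups")
  ns <- lengths(values)
  if (any(ns < 1) || sum(ns) < 3) stop("each group needs n >= 1, total N >= 3")
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(seq_along(values), ns))
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, degenerate = TRUE))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value, degenerate = FALSE)
}

#' Dunn's post hoc pairwise test with Sidak adjustment
#'
#' Pooled-rank z statistic for one group pair with the tie-corrected variance
#' \eqn{(N(N+1)/12 - T/(12(N-1)))(1/n_a + 1/n_b)}, where
#' \eqn{T = \sum (t^3 - t)} over tie groups; the two-sided p-value is Sidak
#' adjusted for \code{m} comparisons: \eqn{p_{adj} = 1 - (1 - p)^m}, capped
#' at 1. Ranks are computed over all supplied groups (the full pooled
#' sample), not just the tested pair.
#'
#' @param values list of numeric per-group samples (all groups of the global
#'   test).
#' @param pair integer or character length-2 selector of the compared groups.
#' @param m number of comparisons in the family (default 3, all pairs of
#'   three groups).
#' @return list with \code{z}, \code{p_raw} and \code{p_adj}.
#' @export
dunn_sidak <- function(values, pair, m = 3) {
  stopifnot(length(pair) == 2, m >= 1)
  if (is.character(pair)) pair <- match(pair, names(values))
  ns <- lengths(values)
  if (any(ns[pair] < 1)) stop("empty group in tested pair")
  x <- unlist(values, use.names = FALSE)
  g <- rep(seq_along(values), ns)
  rk <- rank(x)
  N <- length(x)
  tie_tab <- table(x)
  Tcorr <- sum(tie_tab^3 - tie_tab)
  v <- (N * (N + 1) / 12 - Tcorr / (12 * (N - 1))) *
       (1 / ns[pair[1]] + 1 / ns[pair[2]])
  diffm <- mean(rk[g == pair[1]]) - mean(rk[g == pair[2]])
  z <- if (v <= 0) 0 else diffm / sqrt(v)
  p_raw <- 2 * stats::pnorm(-abs(z))
  list(z = unname(z), p_raw = unname(p_raw),
       p_adj = min(1, 1 - (1 - p_raw)^m))
}

#' Shapiro-Wilk normality screen per group
#'
#' Reported for completeness only — downstream comparisons always proceed
#' nonparametrically. Groups with n < 3 or constant values yield NA with a
#' warning.
#'
#' @param values list of numeric per-group samples.
#' @return numeric vector of per-group p-values.
#' @export
normality_screen <- function(values) {
  vapply(seq_along(values), function(i) {
    v <- values[[i]]
    if (length(v) < 3 || length(unique(v)) == 1L) {
      warning("normality test undefined for group ", i,
              " (n < 3 or constant)", call. = FALSE)
      return(NA_real_)
    }
    stats::shapiro.test(v)$p.value
  }, numeric(1))
}

#' Subtype feature screen
#'
#' For each feature: Shapiro-Wilk normality p per group, the global
#' Kruskal-Wallis test, and — only when the global p is below \code{alpha} —
#' Dunn-Sidak post hoc p-values for the three subtype pairs (PTC vs FTC,
#' PTC vs MTC, MTC vs FTC). Non-significant features keep NA in the post hoc
#' cells, mirroring the dash convention of the screen table.
#'
#' @param table feature data.frame including a \code{subtype} column.
#' @param features feature columns to screen (default
#'   \code{\link{feature_names}} intersected with the table).
#' @param group_col grouping column name.
#' @param alpha global significance level gating the post hoc tests.
#' @return data.frame, one row per feature: \code{kw_H}, \code{kw_p},
#'   \code{significant}, \code{p_PTC_FTC}, \code{p_PTC_MTC},
#'   \code{p_MTC_FTC} and per-group normality p-values.
#' @export
feature_screen <- function(table, features = NULL, group_col = "subtype",
                           alpha = 0.05) {
  if (is.null(features))
    features <- intersect(feature_names(), names(table))
  groups <- c("PTC", "FTC", "MTC")
  groups <- groups[groups %in% unique(table[[group_col]])]
  if (length(groups) < 2) stop("need at least two subtype groups")
  pairs <- list(c("PTC", "FTC"), c("PTC", "MTC"), c("MTC", "FTC"))
  out <- lapply(features, function(f) {
    vals <- lapply(groups, function(gp) {
      v <- table[[f]][table[[group_col]] == gp]
      v[!is.na(v)]
    })
    names(vals) <- groups
    norm_p <- suppressWarnings(normality_screen(vals))
    kw <- if (any(lengths(vals) < 1) || sum(lengths(vals)) < 3) {
      warning("feature ", f, " has empty groups after NA removal", call. = FALSE)
      list(H = NA_real_, p = NA_real_)
    } else kruskal_wallis(vals)
    ph <- rep(NA_real_, 3)
    if (!is.na(kw$p) && kw$p < alpha) {
      ph <- vapply(pairs, function(pr) {
        if (all(pr %in% groups)) dunn_sidak(vals, pr, m = 3)$p_adj else NA_real_
      }, numeric(1))
    }
    df <- data.frame(feature = f, kw_H = kw$H, kw_p = kw$p,
                     significant = !is.na(kw$p) && kw$p < alpha,
                     p_PTC_FTC = ph[1], p_PTC_MTC = ph[2], p_MTC_FTC = ph[3])
    for (i in seq_along(groups))
      df[[paste0("shapiro_p_", groups[i])]] <- norm_p[i]
    df
  })
  do.call(rbind, out)
}

#' Default clinical-interpretability ranking
#'
#' Tie-break ordering used by \code{\link{correlation_prune}} when two
#' correlated features are equally (in)significant: directly interpretable
#' morphology, echogenicity, margin and calcification measures come before
#' the abstract texture descriptors.
#'
#' @return character vector of all canonical features, most interpretable
#'   first.
#' @export
default_interpretability_rank <- function() {
  c("perimeter_to_area", "aspect_ratio",
    "echo_mean", "echo_median",
    "peripheral_calc_count", "micro_density", "macro_density",
    "calcified_area_pct", "cystic_area_pct",
    "profile_mean", "profile_std", "gradient_mean", "gradient_std",
    "kl_divergence",
    "echo_std", "entropy_mean", "entropy_std",
    "glcm_contrast", "glcm_correlation", "glcm_homogeneity", "glcm_energy")
}

#' Prune collinear features
#'
#' Pearson correlations over all feature pairs; features are visited in
#' priority order (screen-significant features first, then the declared
#' interpretability rank) and greedily retained unless their absolute
#' correlation with an already retained feature exceeds \code{threshold}, in
#' which case they are dropped and mapped to that retained partner. Constant
#' or NA-containing columns are excluded up front with a warning.
#'
#' @param table data.frame or matrix of feature columns (features only).
#' @param threshold absolute-correlation cut (default 0.9).
#' @param significant optional character vector of screen-significant
#'   features, prioritized for retention.
#' @param interpretability character ranking used as tie-break (default
#'   \code{\link{default_interpretability_rank}}).
#' @return list with \code{retained}, \code{dropped} (data.frame feature ->
#'   retained partner, with their correlation) and the correlation
#'   \code{matrix}.
#' @export
correlation_prune <- function(table, threshold = 0.9, significant = character(0),
                              interpretability = default_interpretability_rank()) {
  mat <- as.matrix(as.data.frame(table))
  storage.mode(mat) <- "double"
  usable <- apply(mat, 2, function(x) !anyNA(x) && stats::sd(x) > 0)
  if (any(!usable))
    warning("excluding constant/NA feature columns: ",
            paste(colnames(mat)[!usable], collapse = ", "), call. = FALSE)
  mat <- mat[, usable, drop = FALSE]
  if (ncol(mat) < 2) stop("need at least two usable feature columns")
  cm <- stats::cor(mat)
  feats <- colnames(mat)
  rank_interp <- match(feats, interpretability)
  rank_interp[is.na(rank_interp)] <- length(interpretability) + 1L
  ord <- order(!(feats %in% significant), rank_interp)
  retained <- character(0)
  dropped <- data.frame(feature = character(0), partner = character(0),
                        r = numeric(0))
  for (f in feats[ord]) {
    conflicts <- retained[abs(cm[f, retained]) > threshold]
    if (length(conflicts)) {
      best <- conflicts[which.max(abs(cm[f, conflicts]))]
      dropped <- rbind(dropped, data.frame(feature = f, partner = best,
                                           r = cm[f, best]))
    } else retained <- c(retained, f)
  }
  list(retained = retained, dropped = dropped, matrix = cm,
       threshold = threshold)
}
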