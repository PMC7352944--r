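# Midrank AUC: normalized Mann-Whitney U. `positive` is a logical vector.
# Shared by per-feature ranking, classifier evaluation and the robustness
# tests, so cross-test comparisons are on an identical scale.
auc_stat <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                        # midranks for ties
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Principal component analysis with a deterministic sign convention
#'
#' Centered (optionally unit-scaled) SVD-based PCA. Each component's sign is
#' fixed so its largest-magnitude loading is positive, making results
#' reproducible across platforms.
#'
#' @param table a complete [feature_table] or numeric matrix.
#' @param n_components number of components to retain (default: all,
#'   `min(n - 1, p)`).
#' @param scale. divide features by their SD (default FALSE). Constant
#'   features with scaling on are an error unless `drop_constant = TRUE`.
#' @param drop_constant silently exclude zero-variance features when scaling.
#' @return List with `scores`, `loadings` (p x k rotation), `sdev`,
#'   `var_share` (shares over all `min(n-1, p)` components), `center`,
#'   `scale`, `features` (retained feature ids).
#' @export
fit_pca <- function(table, n_components = NULL, scale. = FALSE,
                    drop_constant = FALSE) {
  x <- if (inherits(table, "feature_table")) unclass(table) else as.matrix(table)
  if (anyNA(x)) stop("impute missing values first")
  if (scale.) {
    sdv <- apply(x, 2, stats::sd)
    if (any(sdv == 0)) {
      if (!drop_constant)
        stop("constant feature(s) with scaling on: ",
             paste(colnames(x)[sdv == 0], collapse = ", "))
      x <- x[, sdv > 0, drop = FALSE]
    }
  }
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- kmax
  if (n_components > kmax) stop("n_components exceeds min(n - 1, p)")
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  var_all <- pc$sdev^2
  keep <- seq_len(n_components)
  list(scores = pc$x[, keep, drop = FALSE],
       loadings = pc$rotation[, keep, drop = FALSE],
       sdev = pc$sdev[keep],
       var_share = (var_all / sum(var_all))[seq_len(kmax)],
       center = pc$center,
       scale = if (scale.) pc$scale else NULL,
       features = colnames(x))
}

#' Discriminant analysis of principal components
#'
#' DAPC focuses on between-group variability while neglecting within-group
#' variation: features are z-scored, reduced by PCA, and the retained
#' component scores are fed to a linear discriminant analysis. Each
#' feature's contribution to between-group separation is the
#' eigenvalue-share-weighted sum over discriminant axes of its squared
#' back-projected discriminant loading, normalized to sum to 1.
#'
#' @param table a complete [feature_table].
#' @param labels a [cohort_labels] with >= 2 groups of >= 2 samples.
#' @param n_pcs `"auto"` (smallest count reaching 90% cumulative variance,
#'   capped at `n - n_groups`) or an integer; values above the cap are
#'   clamped with a warning.
#' @param var_target cumulative-variance target for the auto rule.
#' @return An object of class `dapc_model`: centering/scaling vectors, PCA
#'   loadings and variance shares, retained PC count, discriminant axis
#'   coefficients and eigenvalue shares, per-feature `contributions`
#'   (non-negative, summing to 1), and the group scores on the discriminant
#'   axes.
#' @export
fit_dapc <- function(table, labels, n_pcs = "auto", var_target = 0.9) {
  stopifnot(inherits(table, "feature_table"))
  g <- align_labels(table, labels)
  if (nlevels(g) < 2L) stop("DAPC needs >= 2 groups")
  if (any(table(g) < 2L)) stop("each group needs >= 2 samples")
  x <- unclass(table)
  if (anyNA(x)) stop("impute missing values first")
  n <- nrow(x); G <- nlevels(g)
  center <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  scl <- ifelse(sdv > 0, sdv, 1)          # constant features pass through as 0
  z <- sweep(sweep(x, 2, center), 2, scl, "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  nz <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  cap <- max(1L, min(n - G, nz))
  if (identical(n_pcs, "auto")) {
    cum <- cumsum(pc$sdev[seq_len(nz)]^2) / sum(pc$sdev[seq_len(nz)]^2)
    k <- which(cum >= var_target)[1]
    k <- min(k, cap)
  } else {
    k <- as.integer(n_pcs)
    if (k > cap) {
      warning("n_pcs clamped to ", cap)
      k <- cap
    }
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ld <- MASS::lda(scores, grouping = g)
  pred <- stats::predict(ld, scores)
  n_da <- ncol(ld$scaling)                # <= groups - 1
  eig_share <- ld$svd[seq_len(n_da)]^2 / sum(ld$svd[seq_len(n_da)]^2)
  # back-project discriminant axes into feature space
  V <- pc$rotation[, seq_len(k), drop = FALSE] %*% ld$scaling
  contrib <- as.numeric((V^2) %*% eig_share)
  total <- sum(contrib)
  contrib <- if (total > 0) contrib / total else rep(1 / length(contrib),
                                                     length(contrib))
  names(contrib) <- colnames(x)
  structure(list(center = center, scale = scl,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 var_share = pc$sdev[seq_len(nz)]^2 / sum(pc$sdev[seq_len(nz)]^2),
                 n_pcs = k, n_da = n_da,
                 axes = ld$scaling, eig_share = eig_share,
                 contributions = contrib,
                 da_scores = pred$x, groups = g),
            class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("dapc_model: %d PCs retained, %d discriminant axes, %d features\n",
              x$n_pcs, x$n_da, length(x$contributions)))
  invisible(x)
}

new_ranking <- function(method, scores, semantics) {
  ord <- order(-scores, names(scores))    # ties broken by ascending feature id
  structure(list(method = method, scores = scores, semantics = semantics,
                 features = names(scores)[ord]),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking (%s, %s): top = %s\n", x$method, x$semantics,
              paste(utils::head(x$features, 5), collapse = ", ")))
  invisible(x)
}

#' Select features by DAPC contribution
#'
#' Keeps the features whose contribution to between-group variability is at
#' least `threshold` (default 2%), ranked by contribution descending with
#' ties broken by feature id.
#'
#' @param model a [fit_dapc] model.
#' @param threshold minimum contribution share (default 0.02).
#' @return A `feature_ranking` of the selected features (empty, with a
#'   warning, if none reach the threshold). The full contribution vector
#'   remains available in the model.
#' @export
dapc_select <- function(model, threshold = 0.02) {
  stopifnot(inherits(model, "dapc_model"))
  sel <- model$contributions[model$contributions >= threshold]
  if (!length(sel)) warning("no feature reaches the contribution threshold")
  new_ranking("DAPC", sel, "contribution share")
}

# full DAPC ranking over all features (used for panel construction)
dapc_ranking <- function(model) {
  new_ranking("DAPC", model$contributions, "contribution share")
}

#' Random-forest permutation importance ranking
#'
#' Fits a random-forest classifier and ranks features by permutation
#' importance (mean decrease in out-of-bag accuracy). Deterministic under a
#' fixed seed (single-threaded).
#'
#' @param table a complete [feature_table].
#' @param labels group labels (>= 2 classes).
#' @param n_trees number of trees (default 500).
#' @param seed RNG seed.
#' @return A `feature_ranking` with method `"RF"`.
#' @export
rf_importance <- function(table, labels, n_trees = 500, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  g <- align_labels(table, labels)
  if (nlevels(g) < 2L) stop("labels must have >= 2 classes")
  x <- unclass(table)
  if (anyNA(x)) stop("impute missing values first")
  df <- data.frame(.group = g, x, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".group", data = df,
                        num.trees = n_trees, importance = "permutation",
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance[colnames(x)]
  new_ranking("RF", imp, "permutation importance")
}

#' Per-feature AUC ranking
#'
#' For each feature, the area under the ROC curve of the raw feature values
#' against the two class labels, computed as the normalized Mann-Whitney U
#' statistic with midranks for ties. The score is `max(AUC, 1 - AUC)` so the
#' ranking is direction-free.
#'
#' @param table a complete [feature_table].
#' @param labels two-group labels; the second factor level is the positive
#'   class.
#' @return A `feature_ranking` with method `"AUC"`.
#' @export
auc_rank <- function(table, labels) {
  stopifnot(inherits(table, "feature_table"))
  g <- align_labels(table, labels)
  sp <- two_group_split(g)
  x <- unclass(table)
  if (anyNA(x)) stop("impute missing values first")
  pos <- seq_len(nrow(x)) %in% sp$i2
  auc <- apply(x, 2, auc_stat, positive = pos)
  new_ranking("AUC", pmax(auc, 1 - auc), "per-feature AUC (direction-free)")
}

#' Nested candidate panels from a ranking
#'
#' Builds the candidate biomarker panels of sizes `k_min` to `k_max` as
#' nested top-k prefixes of a feature ranking (the field's 3-to-10-variable
#' range; exhaustive subset search over hundreds to thousands of features is
#' combinatorially infeasible and ranked prefixes are what ranked selection
#' implies).
#'
#' @param ranking a `feature_ranking` with at least `k_min` entries.
#' @param k_min,k_max panel size range (defaults 3 and 10).
#' @return List of `feature_panel` objects (`features`, `method`, `rule`).
#' @export
candidate_panels <- function(ranking, k_min = 3, k_max = 10) {
  stopifnot(inherits(ranking, "feature_ranking"))
  nf <- length(ranking$features)
  if (nf < k_min) stop("ranking has fewer than k_min features")
  lapply(seq(k_min, min(k_max, nf)), function(k)
    structure(list(features = ranking$features[seq_len(k)],
                   method = ranking$method,
                   rule = sprintf("top-%d", k)),
              class = "feature_panel"))
}

#' @export
print.feature_panel <- function(x, ...) {
  cat(sprintf("feature_panel [%s, %s]: %s\n", x$method, x$rule,
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Write feature rankings / panels as text
#'
#' Tab-separated `feature, method, score, rank`.
#' @param ranking a `feature_ranking`.
#' @param path file path.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(feature = ranking$features,
                   method = ranking$method,
                   score = ranking$scores[ranking$features],
                   rank = seq_along(ranking$features))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
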