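# ridge-penalized logistic regression by IRLS: the "Bayesian GLM" family is
# realized as a Gaussian(0, 1/lambda) prior on standardized coefficients,
# the weakly-informative-prior behaviour that keeps separable fits finite.
ridge_logistic <- function(x, y, lambda = 0.01, maxit = 100, tol = 1e-9) {
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)  # intercept unpenalized
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    zz <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + pen
    beta_new <- solve(H, crossprod(X, w * zz))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

default_tuning <- function(algorithm) {
  switch(algorithm,
    NN     = list(size = c(1, 3, 5), decay = c(0.001, 0.01, 0.1)),
    BGLM   = list(lambda = 0.01),
    C5TREE = list(cp = c(0.001, 0.01, 0.05)),
    RF     = list(num_trees = 300, mtry_frac = c(0.5, 1)))
}

tuning_grid <- function(tuning) {
  grid <- expand.grid(tuning, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid[do.call(order, grid), , drop = FALSE]
}

fit_one <- function(algorithm, x, y01, par, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  switch(algorithm,
    NN = nnet::nnet(x, y01, size = par$size, decay = par$decay,
                    entropy = TRUE, maxit = 200, trace = FALSE,
                    MaxNWts = 10000),
    BGLM = ridge_logistic(x, y01, lambda = par$lambda),
    C5TREE = {
      df <- data.frame(.y = factor(y01), x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(cp = par$cp, xval = 0,
                                                  minsplit = 10))
    },
    RF = {
      mtry <- max(1L, floor(ncol(x) * par$mtry_frac))
      df <- data.frame(.y = factor(y01), x, check.names = FALSE)
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = par$num_trees, mtry = mtry,
                     probability = TRUE, seed = seed, num.threads = 1)
    })
}

score_one <- function(algorithm, fit, x) {
  switch(algorithm,
    NN = as.numeric(stats::predict(fit, x)),
    BGLM = {
      eta <- drop(cbind(1, x) %*% fit)
      1 / (1 + exp(-eta))
    },
    C5TREE = {
      df <- as.data.frame(x, check.names = FALSE)
      as.numeric(stats::predict(fit, df)[, "1"])
    },
    RF = {
      df <- as.data.frame(x, check.names = FALSE)
      as.numeric(stats::predict(fit, data = df, num.threads = 1)$predictions[, "1"])
    })
}

stratified_folds <- function(y01, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- sample(which(y01 == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a classifier on a synthetic cohort over a feature panel
#'
#' Inputs are restricted to the panel's features and z-scored by the
#' training moments (the identical standardization is applied at prediction
#' time). When the tuning grid has more than one point, hyperparameters are
#' chosen by stratified k-fold cross-validation on the training cohort
#' maximizing AUC; a single-point grid is fitted directly. Supported
#' algorithm families: `NN` (single-hidden-layer neural network), `BGLM`
#' (ridge-regularized Bayesian-style logistic regression), `C5TREE`
#' (information-gain decision tree with pruning-complexity grid), `RF`
#' (probability random forest). The RF classifier is only accepted together
#' with an RF-sourced panel: it serves as the reference algorithm challenged
#' with its own feature list.
#'
#' @param train a `synthetic_cohort` or list with `table` and `labels`
#'   (binary).
#' @param panel a `feature_panel`.
#' @param algorithm one of `"NN"`, `"BGLM"`, `"C5TREE"`, `"RF"`.
#' @param tuning named list of hyperparameter vectors overriding the
#'   defaults.
#' @param cv_folds cross-validation folds used when tuning (default 5).
#' @param seed RNG seed; same inputs + seed give an identical tuning trace
#'   and parameters.
#' @return An object of class `trained_model`: algorithm, panel,
#'   standardization vectors, fitted parameters, positive class, tuning
#'   trace, seed.
#' @export
train_model <- function(train, panel, algorithm = c("NN", "BGLM", "C5TREE", "RF"),
                        tuning = NULL, cv_folds = 5, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(panel, "feature_panel"))
  if (algorithm == "RF" && !identical(panel$method, "RF"))
    stop("the RF classifier is only challenged with RF-sourced panels ",
         "(reference-algorithm pairing rule)")
  table <- train$table; labels <- train$labels
  g <- align_labels(table, labels)
  if (nlevels(g) != 2L) stop("binary labels are required")
  x <- unclass(table)
  miss <- setdiff(panel$features, colnames(x))
  if (length(miss)) stop("panel features absent from table: ",
                         paste(miss, collapse = ", "))
  x <- x[, panel$features, drop = FALSE]
  if (anyNA(x)) stop("impute missing values first")
  positive <- levels(g)[2]
  y01 <- as.integer(g == positive)
  center <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  scl <- ifelse(sdv > 0, sdv, 1)
  z <- sweep(sweep(x, 2, center), 2, scl, "/")
  # syntactic internal names: bucket-style feature ids (e.g. "0.2650") are
  # legal table columns but not legal model-formula variables
  colnames(z) <- paste0("V", seq_len(ncol(z)))
  grid <- tuning_grid(tuning %||% default_tuning(algorithm))
  trace <- NULL
  if (nrow(grid) > 1L) {
    fold <- stratified_folds(y01, cv_folds, seed)
    cv_auc <- vapply(seq_len(nrow(grid)), function(i) {
      par <- as.list(grid[i, , drop = FALSE])
      aucs <- vapply(seq_len(cv_folds), function(fi) {
        tr <- fold != fi; te <- !tr
        if (length(unique(y01[te])) < 2L) return(NA_real_)
        fit <- fit_one(algorithm, z[tr, , drop = FALSE], y01[tr], par,
                       seed + 1000L * fi + i)
        auc_stat(score_one(algorithm, fit, z[te, , drop = FALSE]),
                 y01[te] == 1L)
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    trace <- cbind(grid, cv_auc = cv_auc)
    best <- which.max(cv_auc)
  } else best <- 1L
  par <- as.list(grid[best, , drop = FALSE])
  fit <- fit_one(algorithm, z, y01, par, seed)
  structure(list(algorithm = algorithm, panel = panel,
                 center = center, scale = scl, fit = fit,
                 best_par = par, tuning_trace = trace,
                 positive = positive, levels = levels(g),
                 seed = as.integer(seed)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model: %s on %d-feature %s panel (positive = %s)\n",
              x$algorithm, length(x$panel$features), x$panel$method,
              x$positive))
  invisible(x)
}

#' Predict class-1 scores
#'
#' Applies a trained model to a table, returning per-sample scores in
#' `[0, 1]` (class probabilities, or tree/forest vote shares). Columns
#' outside the model's panel are ignored; a missing panel feature is an
#' error.
#'
#' @param model a `trained_model`.
#' @param table a [feature_table] (or matrix with feature columns).
#' @return Named numeric vector of scores for the model's positive class.
#' @export
predict_scores <- function(model, table) {
  stopifnot(inherits(model, "trained_model"))
  x <- if (inherits(table, "feature_table")) unclass(table) else as.matrix(table)
  miss <- setdiff(model$panel$features, colnames(x))
  if (length(miss)) stop("panel features absent from table: ",
                         paste(miss, collapse = ", "))
  x <- x[, model$panel$features, drop = FALSE]
  if (anyNA(x)) stop("impute missing values first")
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  colnames(z) <- paste0("V", seq_len(ncol(z)))
  s <- score_one(model$algorithm, model$fit, z)
  stats::setNames(pmin(pmax(s, 0), 1), rownames(x))
}

#' Evaluate classifier scores against labels
#'
#' AUC by the midrank Mann-Whitney statistic (equal to the trapezoidal area
#' under the ROC sweep). The operating threshold maximizes the Youden index
#' J = sensitivity + specificity - 1; ties are resolved towards higher
#' specificity (the higher threshold). Samples scoring at or above the
#' threshold are called positive.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels; the second factor level (or `positive`) is
#'   the positive class.
#' @param positive optional positive class name.
#' @return An object of class `eval_result`: `auc`, `roc` (threshold, FPR,
#'   TPR sweep), `threshold`, `sensitivity`, `specificity`, `confusion`
#'   counts.
#' @export
evaluate_classifier <- function(scores, labels, positive = NULL) {
  lev <- if (is.factor(labels)) levels(droplevels(labels))
         else unique(as.character(labels))
  f <- factor(as.character(labels), levels = lev)
  if (nlevels(f) != 2L) stop("two classes are required")
  if (is.null(positive)) positive <- levels(f)[2]
  pos <- f == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  auc <- auc_stat(scores, pos)
  thr <- c(sort(unique(scores)), Inf)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  j <- tpr - fpr
  best <- which(j >= max(j) - 1e-12)
  best <- best[length(best)]              # highest threshold: more specific
  pred_pos <- scores >= thr[best]
  tp <- sum(pred_pos & pos); fn <- sum(!pred_pos & pos)
  tn <- sum(!pred_pos & !pos); fp <- sum(pred_pos & !pos)
  structure(list(auc = auc,
                 roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 threshold = thr[best],
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 positive = positive),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("AUC %.3f, sensitivity %.1f%%, specificity %.1f%% (threshold %.3g)\n",
              x$auc, 100 * x$sensitivity, 100 * x$specificity, x$threshold))
  invisible(x)
}

#' Select the best feature-set x algorithm combination
#'
#' Maximum validation AUC; ties broken by fewer panel features, then higher
#' sensitivity, then lexicographic algorithm name.
#'
#' @param combos non-empty list of combo results, each a list with `panel`,
#'   `algorithm`, `eval` (an `eval_result`).
#' @return The winning combo, with a `rank` field added to every element of
#'   the input list (returned invisibly via attribute `leaderboard`).
#' @export
select_best_combo <- function(combos) {
  if (!length(combos)) stop("empty combo list")
  key <- function(cb) c(-cb$eval$auc, length(cb$panel$features),
                        -cb$eval$sensitivity)
  mat <- t(vapply(combos, key, numeric(3)))
  ord <- order(mat[, 1], mat[, 2], mat[, 3],
               vapply(combos, function(cb) cb$algorithm, character(1)))
  best <- combos[[ord[1]]]
  best$rank <- 1L
  attr(best, "leaderboard") <- combos[ord]
  best
}
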