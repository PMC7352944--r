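# Shared engine for the column-permutation tests (2, 3 and 4): each round
# independently permutes the listed panel features across samples, re-applies
# the model, and compares the permuted-data AUC with the observed one.
# Using one engine makes test 2 and test 3 coincide exactly for a
# single-feature panel under a shared seed.
permute_columns_test <- function(model, x, pos, cols, n_perm, seed) {
  obs <- auc_stat(predict_scores(model, x), pos)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(x)
  b <- 0L
  for (m in seq_len(n_perm)) {
    xp <- x
    for (j in cols) xp[, j] <- xp[sample.int(n), j]
    if (auc_stat(predict_scores(model, xp), pos) >= obs - 1e-12) b <- b + 1L
  }
  list(observed_auc = obs, p_value = (b + 1) / (n_perm + 1))
}

validation_matrix <- function(model, table, labels) {
  x <- if (inherits(table, "feature_table")) unclass(table) else as.matrix(table)
  g <- align_labels(x, labels)
  if (nlevels(g) != 2L) stop("binary labels are required")
  if (!model$positive %in% levels(g))
    stop("model's positive class absent from labels")
  list(x = x[, model$panel$features, drop = FALSE], pos = g == model$positive)
}

#' Test 1: label-permutation significance of the observed AUC
#'
#' The model's scores on the validation data are computed once; each round
#' the labels are shuffled and the AUC of the unchanged scores is recomputed.
#' The add-one p-value is the chance of randomly predicting the data as well
#' as the model does. The model is deliberately not refitted per
#' permutation: refitting under shuffled labels is what Test 5 covers.
#'
#' @param model a `trained_model`.
#' @param table validation [feature_table].
#' @param labels binary validation labels.
#' @param n_perm permutations (default 999, >= 1).
#' @param seed RNG seed.
#' @return List with `observed_auc` and `p_value` (always > 0).
#' @export
test1_label_permutation <- function(model, table, labels, n_perm = 999,
                                    seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  v <- validation_matrix(model, table, labels)
  scores <- predict_scores(model, v$x)
  obs <- auc_stat(scores, v$pos)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  b <- 0L
  for (m in seq_len(n_perm))
    if (auc_stat(scores, sample(v$pos)) >= obs - 1e-12) b <- b + 1L
  list(observed_auc = obs, p_value = (b + 1) / (n_perm + 1))
}

#' Test 2: dependence of the model on one feature's true values
#'
#' Randomly reorders feature `feature`'s values across the whole cohort each
#' round and re-applies the model. A small p means performance depends on
#' that feature's true values (equivalently: how a corrupted measurement of
#' the feature would hurt the prediction).
#'
#' @inheritParams test1_label_permutation
#' @param feature a feature id inside the model's panel.
#' @return List with `observed_auc` and `p_value`.
#' @export
test2_variable_noise <- function(model, table, labels, feature, n_perm = 999,
                                 seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!feature %in% model$panel$features)
    stop("feature is not in the model's panel")
  v <- validation_matrix(model, table, labels)
  permute_columns_test(model, v$x, v$pos, feature, n_perm, seed)
}

#' Test 3: background (noise) prediction level of the model
#'
#' Every panel feature is independently permuted each round, destroying the
#' data structure entirely; the p-value is the chance of the model doing as
#' well on unstructured data. A small p demonstrates that the real data is
#' structured.
#'
#' @inheritParams test1_label_permutation
#' @return List with `observed_auc` and `p_value`.
#' @export
test3_all_noise <- function(model, table, labels, n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  v <- validation_matrix(model, table, labels)
  permute_columns_test(model, v$x, v$pos, model$panel$features, n_perm, seed)
}

#' Test 4: predictive capacity of a single feature amid noise
#'
#' Feature `feature` is kept intact while all other panel features are
#' permuted each round. A small p here would mean that feature alone can
#' carry the prediction through noise; typically none of the selected
#' features alone accurately classifies the samples, so moderate-to-large
#' values are the expected outcome.
#'
#' @inheritParams test2_variable_noise
#' @return List with `observed_auc` and `p_value`.
#' @export
test4_single_variable_signal <- function(model, table, labels, feature,
                                         n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!feature %in% model$panel$features)
    stop("feature is not in the model's panel")
  if (length(model$panel$features) < 2L)
    stop("test 4 is undefined for a single-feature panel")
  v <- validation_matrix(model, table, labels)
  permute_columns_test(model, v$x, v$pos,
                       setdiff(model$panel$features, feature), n_perm, seed)
}

#' Test 5: overfitting check of the whole synthetic-data pipeline
#'
#' The synthetic training data outnumbers the validation set and is simulated
#' from sample moments, so the pipeline could in principle manufacture
#' predictive-looking models out of nothing. Each shuffle permutes the labels
#' of the real table, re-estimates per-(shuffled-)group moments, regenerates
#' synthetic data, redoes feature selection and training, and validates the
#' resulting model on the shuffled-label real table. The add-one p-value
#' compares the real-pipeline AUC with the shuffled-pipeline AUC sample.
#' Shuffled-pipeline AUCs materially above 0.5 on their own shuffled labels
#' expose the moment-estimation leakage inherent in validating on the same
#' samples the moments came from; the full AUC sample is returned so this
#' diagnostic is visible, not hidden.
#'
#' @param table real [feature_table] (complete).
#' @param labels binary labels.
#' @param config a [pipeline_config] describing augmentation size, selection
#'   method and algorithm for the refits.
#' @param n_shuffles number of label shuffles (default 49, >= 1).
#' @param seed RNG seed.
#' @return List with `real_auc`, `shuffled_auc` (numeric vector) and
#'   `p_value`.
#' @export
test5_overfit_check <- function(table, labels, config = pipeline_config(),
                                n_shuffles = 49, seed = 1L) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  g <- align_labels(table, labels)
  real_auc <- pipeline_fit_once(table, g, config, seed)$eval$auc
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  shuffled <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    set.seed(seed + 7919L * s)
    gs <- cohort_labels(sample(as.character(g)), names(g))
    shuffled[s] <- pipeline_fit_once(table, align_labels(table, gs), config,
                                     seed + 7919L * s)$eval$auc
  }
  list(real_auc = real_auc, shuffled_auc = shuffled,
       p_value = (sum(shuffled >= real_auc - 1e-12) + 1) / (n_shuffles + 1))
}

#' Run all five robustness tests on a selected model
#'
#' Tests 1-4 evaluate the fixed model on the validation table; Test 5 reruns
#' the reduced pipeline under label shuffles. Sub-seeds for each test are
#' derived deterministically from `seed` and recorded.
#'
#' @param model the winning `trained_model`.
#' @param table validation [feature_table].
#' @param labels binary labels.
#' @param config [pipeline_config] for Test 5; `NULL` skips Test 5.
#' @param n_perm permutations for tests 1-4 (default 999).
#' @param n_shuffles shuffles for Test 5 (default 49).
#' @param seed master seed.
#' @return An object of class `robustness_report` with `test1_p`,
#'   per-feature `test2_p` and `test4_p`, `test3_p`, `test5` (real AUC,
#'   shuffled AUC sample, p), `n_perm`, `seeds`.
#' @export
robustness_report <- function(model, table, labels, config = NULL,
                              n_perm = 999, n_shuffles = 49, seed = 1L) {
  feats <- model$panel$features
  seeds <- list(test1 = seed + 11L, test2 = seed + 22L + seq_along(feats),
                test3 = seed + 33L, test4 = seed + 44L + seq_along(feats),
                test5 = seed + 55L)
  t1 <- test1_label_permutation(model, table, labels, n_perm, seeds$test1)
  t2 <- vapply(seq_along(feats), function(i)
    test2_variable_noise(model, table, labels, feats[i], n_perm,
                         seeds$test2[i])$p_value, numeric(1))
  t3 <- test3_all_noise(model, table, labels, n_perm, seeds$test3)
  t4 <- if (length(feats) >= 2L)
    vapply(seq_along(feats), function(i)
      test4_single_variable_signal(model, table, labels, feats[i], n_perm,
                                   seeds$test4[i])$p_value, numeric(1))
  else rep(NA_real_, length(feats))
  t5 <- if (!is.null(config))
    test5_overfit_check(table, labels, config, n_shuffles, seeds$test5)
  else NULL
  structure(list(observed_auc = t1$observed_auc,
                 test1_p = t1$p_value,
                 test2_p = stats::setNames(t2, feats),
                 test3_p = t3$p_value,
                 test4_p = stats::setNames(t4, feats),
                 test5 = t5,
                 n_perm = n_perm, n_shuffles = n_shuffles, seeds = seeds),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness_report (observed AUC %.3f, %d permutations)\n",
              x$observed_auc, x$n_perm))
  cat(sprintf("  test 1 (label permutation)    p = %.4g\n", x$test1_p))
  cat(sprintf("  test 2 (per-variable noise)   p in [%.4g, %.4g]\n",
              min(x$test2_p), max(x$test2_p)))
  cat(sprintf("  test 3 (all-noise background) p = %.4g\n", x$test3_p))
  if (!all(is.na(x$test4_p)))
    cat(sprintf("  test 4 (single-variable)      p in [%.4g, %.4g]\n",
                min(x$test4_p), max(x$test4_p)))
  if (!is.null(x$test5))
    cat(sprintf("  test 5 (pipeline overfit)     real AUC %.3f vs shuffled mean %.3f, p = %.4g\n",
                x$test5$real_auc, mean(x$test5$shuffled_auc), x$test5$p_value))
  invisible(x)
}

#' Write a robustness report as a flat summary table
#'
#' Tab-separated `test, feature, value` rows.
#' @param report a `robustness_report`.
#' @param path file path.
#' @export
write_robustness <- function(report, path) {
  rows <- rbind(
    data.frame(test = "observed_auc", feature = NA, value = report$observed_auc),
    data.frame(test = "test1_p", feature = NA, value = report$test1_p),
    data.frame(test = "test2_p", feature = names(report$test2_p),
               value = unname(report$test2_p)),
    data.frame(test = "test3_p", feature = NA, value = report$test3_p),
    data.frame(test = "test4_p", feature = names(report$test4_p),
               value = unname(report$test4_p)))
  if (!is.null(report$test5))
    rows <- rbind(rows,
      data.frame(test = c("test5_real_auc", "test5_p"), feature = NA,
                 value = c(report$test5$real_auc, report$test5$p_value)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
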