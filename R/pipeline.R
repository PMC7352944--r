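#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end flow: imputation, augmentation,
#' feature selection, the training grid, and the robustness tests. All
#' derived seeds are deterministic functions of the master seed supplied to
#' [run_pipeline].
#'
#' @param impute_k neighbours for kNN imputation (default 5).
#' @param log_transform log-transform the (imputed) abundance tables before
#'   any multivariate step (default TRUE): moment estimation, synthetic
#'   generation, selection, training and validation then all operate on the
#'   log scale, the standard scale for right-skewed omics intensities. Set
#'   FALSE for tables already on a symmetric scale, or to generate
#'   integer-kind (count-scale) synthetic data.
#' @param synthetic_n synthetic samples per group (default 500).
#' @param mode synthetic table kind; `NULL` inherits the input table's kind.
#' @param selection_methods subset of `c("DAPC", "RF", "AUC")`.
#' @param dapc_threshold contribution threshold reported for the DAPC
#'   selection rule (default 0.02).
#' @param k_min,k_max candidate panel size range (defaults 3 and 10).
#' @param algorithms classifier families challenged with every panel
#'   (default `c("NN", "BGLM", "C5TREE")`); the RF classifier is added
#'   automatically for RF-sourced panels when `include_rf` is TRUE.
#' @param include_rf include the RF reference classifier on its own panels.
#' @param tuning named list of per-algorithm tuning grids overriding the
#'   defaults, e.g. `list(NN = list(size = 3, decay = 0.01))`.
#' @param cv_folds cross-validation folds during tuning.
#' @param rf_trees trees for the RF importance ranking.
#' @param n_perm permutations for robustness tests 1-4.
#' @param n_shuffles label shuffles for robustness test 5.
#' @param run_robustness run the five tests on the winner (default TRUE).
#' @param refit_method,refit_k,refit_algorithm the single selection route
#'   used when Test 5 refits the pipeline under shuffled labels; `NULL`
#'   means "use the winning combo's route".
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(impute_k = 5, log_transform = TRUE,
                            synthetic_n = 500, mode = NULL,
                            selection_methods = c("DAPC", "RF", "AUC"),
                            dapc_threshold = 0.02, k_min = 3, k_max = 10,
                            algorithms = c("NN", "BGLM", "C5TREE"),
                            include_rf = TRUE, tuning = list(),
                            cv_folds = 5, rf_trees = 500,
                            n_perm = 999, n_shuffles = 49,
                            run_robustness = TRUE,
                            refit_method = NULL, refit_k = NULL,
                            refit_algorithm = NULL) {
  selection_methods <- match.arg(selection_methods,
                                 c("DAPC", "RF", "AUC"), several.ok = TRUE)
  algorithms <- match.arg(algorithms, c("NN", "BGLM", "C5TREE"),
                          several.ok = TRUE)
  if (k_min < 3 || k_max > 10 || k_min > k_max)
    stop("panel sizes must satisfy 3 <= k_min <= k_max <= 10")
  structure(list(impute_k = impute_k, log_transform = log_transform,
                 synthetic_n = synthetic_n, mode = mode,
                 selection_methods = selection_methods,
                 dapc_threshold = dapc_threshold,
                 k_min = k_min, k_max = k_max,
                 algorithms = algorithms, include_rf = include_rf,
                 tuning = tuning, cv_folds = cv_folds, rf_trees = rf_trees,
                 n_perm = n_perm, n_shuffles = n_shuffles,
                 run_robustness = run_robustness,
                 refit_method = refit_method, refit_k = refit_k,
                 refit_algorithm = refit_algorithm),
            class = "pipeline_config")
}

rank_features <- function(method, table, labels, config, seed) {
  switch(method,
    DAPC = dapc_ranking(fit_dapc(table, labels)),
    RF = rf_importance(table, labels, n_trees = config$rf_trees, seed = seed),
    AUC = auc_rank(table, labels))
}

# One pass of moments -> synthetic -> single-route selection -> training ->
# validation on the supplied real table. Used by robustness Test 5.
pipeline_fit_once <- function(table, labels, config, seed) {
  if (isTRUE(config$log_transform)) table <- log_transform(table)
  moments <- estimate_moments(table, labels)
  syn <- generate_synthetic(moments, n_per_group = config$synthetic_n,
                            mode = config$mode, seed = seed + 101L)
  method <- config$refit_method %||% config$selection_methods[1]
  k <- config$refit_k %||% config$k_max
  algorithm <- config$refit_algorithm %||%
    (if (identical(method, "RF")) "RF" else config$algorithms[1])
  ranking <- rank_features(method, syn$table, syn$labels, config, seed + 202L)
  k <- min(k, length(ranking$features))
  panel <- candidate_panels(ranking, k_min = min(3, k), k_max = max(3, k))
  panel <- panel[[length(panel)]]
  model <- train_model(syn, panel, algorithm,
                       tuning = config$tuning[[algorithm]],
                       cv_folds = config$cv_folds, seed = seed + 303L)
  scores <- predict_scores(model, table)
  list(model = model,
       eval = evaluate_classifier(scores, labels, positive = model$positive))
}

#' Run the full discovery pipeline
#'
#' Executes the end-to-end flow on a real (or fixture) cohort: imputation,
#' multivariate overview (PCA and DAPC of the real data), per-group moment
#' estimation, synthetic cohort generation, per-method feature rankings and
#' nested candidate panels computed on the synthetic data, training of every
#' panel x algorithm combination on the synthetic cohort (plus the RF
#' reference classifier on RF-sourced panels), validation of every model on
#' the real table, selection of the best combination, and the five
#' permutation robustness tests on the winner. Reruns with the same inputs,
#' config and seed are identical.
#'
#' By design the validation table is the real table the moments were
#' estimated from, mirroring the train-on-synthetic / validate-on-real flow;
#' pass `validation` / `validation_labels` for a clean held-out variant
#' (e.g. when calibrating the pipeline's null behaviour).
#'
#' @param table real [feature_table].
#' @param labels binary [cohort_labels].
#' @param config a [pipeline_config].
#' @param seed master seed; every stage seed derives from it.
#' @param validation,validation_labels optional independent validation
#'   cohort; default is the (imputed) real table itself.
#' @param output_dir optional directory; when given, the config snapshot,
#'   moments, rankings, leaderboard, best-combo summary and robustness
#'   report are written there as text files.
#' @return An object of class `pipeline_result`: `overview` (PCA variance
#'   shares, DAPC contributions on real data), `moments`, `synthetic`
#'   provenance, `rankings`, `leaderboard` (one row per combo),
#'   `best` (winning combo with model and `eval_result`), `robustness`
#'   (a [robustness_report] or NULL), `config`, `seed`.
#' @export
run_pipeline <- function(table, labels, config = pipeline_config(),
                         seed = 1L, validation = NULL,
                         validation_labels = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  g <- align_labels(table, labels)       # errors before any compute
  if (nlevels(g) != 2L)
    stop("the classification pipeline requires exactly two groups")
  t0 <- Sys.time()
  log_lines <- character()
  log_stage <- function(msg) {
    line <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  if (anyNA(unclass(table))) {
    log_stage("imputing missing values")
    table <- impute_missing(table, k = config$impute_k)
  }
  if (isTRUE(config$log_transform)) {
    log_stage("log-transforming abundances")
    table <- log_transform(table)
  }
  if (is.null(validation)) {
    validation <- table
    validation_labels <- g
  } else {
    validation_labels <- align_labels(validation, validation_labels)
    if (anyNA(unclass(validation)))
      validation <- impute_missing(validation, k = config$impute_k)
    if (isTRUE(config$log_transform))
      validation <- log_transform(validation)
  }

  log_stage("multivariate overview (PCA + DAPC on real data)")
  pca <- fit_pca(table, n_components = min(nrow(table) - 1L, 10L),
                 scale. = TRUE, drop_constant = TRUE)
  dapc_real <- fit_dapc(table, g)
  overview <- list(pca_var_share = pca$var_share,
                   dapc_contributions = dapc_real$contributions,
                   dapc_selected = names(
                     dapc_real$contributions[dapc_real$contributions >=
                                               config$dapc_threshold]))

  log_stage("estimating per-group moments")
  moments <- estimate_moments(table, g)

  log_stage(sprintf("generating synthetic cohort (%d per group)",
                    config$synthetic_n))
  syn <- generate_synthetic(moments, n_per_group = config$synthetic_n,
                            mode = config$mode, seed = seed + 101L)

  log_stage("feature selection on synthetic data")
  rankings <- lapply(stats::setNames(config$selection_methods,
                                     config$selection_methods),
                     function(m) rank_features(m, syn$table, syn$labels,
                                               config, seed + 202L))

  log_stage("training panel x algorithm grid")
  combos <- list()
  ci <- 0L
  for (m in names(rankings)) {
    panels <- candidate_panels(rankings[[m]], config$k_min, config$k_max)
    algos <- config$algorithms
    if (identical(m, "RF") && config$include_rf) algos <- c(algos, "RF")
    for (panel in panels) {
      for (alg in algos) {
        ci <- ci + 1L
        model <- train_model(syn, panel, alg,
                             tuning = config$tuning[[alg]],
                             cv_folds = config$cv_folds,
                             seed = seed + 1000L + ci)
        ev <- evaluate_classifier(predict_scores(model, validation),
                                  validation_labels,
                                  positive = model$positive)
        combos[[ci]] <- list(panel = panel, algorithm = alg,
                             model = model, eval = ev)
      }
    }
  }

  best <- select_best_combo(combos)
  ordered <- attr(best, "leaderboard")
  leaderboard <- data.frame(
    rank = seq_along(ordered),
    method = vapply(ordered, function(cb) cb$panel$method, character(1)),
    panel_size = vapply(ordered, function(cb) length(cb$panel$features),
                        integer(1)),
    algorithm = vapply(ordered, function(cb) cb$algorithm, character(1)),
    auc = vapply(ordered, function(cb) cb$eval$auc, numeric(1)),
    sensitivity = vapply(ordered, function(cb) cb$eval$sensitivity, numeric(1)),
    specificity = vapply(ordered, function(cb) cb$eval$specificity, numeric(1)),
    features = vapply(ordered, function(cb)
      paste(cb$panel$features, collapse = ","), character(1)))
  log_stage(sprintf("best combo: %s / %s panel of %d (validation AUC %.3f)",
                    best$algorithm, best$panel$method,
                    length(best$panel$features), best$eval$auc))

  robustness <- NULL
  if (config$run_robustness) {
    log_stage("robustness tests 1-5 on the winner")
    refit_cfg <- config
    refit_cfg$log_transform <- FALSE   # robustness tables are pre-transformed
    refit_cfg$refit_method <- config$refit_method %||% best$panel$method
    refit_cfg$refit_k <- config$refit_k %||% length(best$panel$features)
    refit_cfg$refit_algorithm <- config$refit_algorithm %||% best$algorithm
    robustness <- robustness_report(best$model, validation, validation_labels,
                                    config = refit_cfg,
                                    n_perm = config$n_perm,
                                    n_shuffles = config$n_shuffles,
                                    seed = seed + 5000L)
  }

  result <- structure(
    list(overview = overview, moments = moments,
         synthetic_provenance = syn$provenance,
         rankings = rankings, leaderboard = leaderboard, best = best,
         robustness = robustness, config = config, seed = as.integer(seed),
         log = log_lines),
    class = "pipeline_result")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    snapshot <- c(unclass(config), list(master_seed = seed))
    snapshot$tuning <- NULL   # grids can hold vectors; stored separately
    yaml::write_yaml(snapshot, file.path(output_dir, "config.yaml"))
    write_moments(moments, file.path(output_dir, "moments.yaml"))
    for (m in names(rankings))
      write_ranking(rankings[[m]],
                    file.path(output_dir, sprintf("ranking_%s.tsv", m)))
    utils::write.table(leaderboard, file.path(output_dir, "leaderboard.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(robustness))
      write_robustness(robustness, file.path(output_dir, "robustness.tsv"))
    writeLines(log_lines, file.path(output_dir, "run.log"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  combos evaluated: %d\n", nrow(x$leaderboard)))
  cat(sprintf("  best: %s on %s top-%d panel\n", x$best$algorithm,
              x$best$panel$method, length(x$best$panel$features)))
  print(x$best$eval)
  if (!is.null(x$robustness)) print(x$robustness)
  invisible(x)
}
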