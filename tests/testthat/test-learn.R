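algorithms <- c("NN", "BGLM", "C5TREE")

test_that("every algorithm separates a perfectly separating feature", {
  sep <- separable_table(n_per_group = 15, seed = 6)
  panel <- panel_of("f01")
  for (alg in algorithms) {
    model <- train_model(sep, panel, alg,
                         tuning = switch(alg, NN = list(size = 3, decay = 0.01),
                                         BGLM = list(lambda = 0.01),
                                         C5TREE = list(cp = 0.01)),
                         seed = 2)
    ev <- evaluate_classifier(predict_scores(model, sep$table), sep$labels,
                              positive = model$positive)
    expect_equal(ev$auc, 1, info = alg)
  }
  rf_model <- train_model(sep, panel_of("f01", method = "RF"), "RF",
                          tuning = list(num_trees = 100, mtry_frac = 1),
                          seed = 2)
  ev <- evaluate_classifier(predict_scores(rf_model, sep$table), sep$labels,
                            positive = rf_model$positive)
  expect_equal(ev$auc, 1)
})

test_that("the RF classifier is only paired with RF-sourced panels", {
  sep <- separable_table(seed = 7)
  expect_error(train_model(sep, panel_of("f01", method = "DAPC"), "RF"),
               "RF-sourced")
})

test_that("ridge regularization keeps separable BGLM fits finite", {
  sep <- separable_table(n_per_group = 10, seed = 8)
  model <- train_model(sep, panel_of("f01"), "BGLM",
                       tuning = list(lambda = 0.01), seed = 1)
  expect_true(all(is.finite(model$fit)))
})

test_that("training is deterministic, including the tuning trace", {
  sep <- separable_table(n_per_group = 12, n_noise = 4, gap = 1.5, seed = 9)
  panel <- panel_of(c("f01", "f02", "f03"))
  m1 <- train_model(sep, panel, "NN",
                    tuning = list(size = c(1, 3), decay = c(0.01, 0.1)),
                    cv_folds = 3, seed = 5)
  m2 <- train_model(sep, panel, "NN",
                    tuning = list(size = c(1, 3), decay = c(0.01, 0.1)),
                    cv_folds = 3, seed = 5)
  expect_identical(m1$tuning_trace, m2$tuning_trace)
  expect_identical(m1$best_par, m2$best_par)
  expect_identical(predict_scores(m1, sep$table), predict_scores(m2, sep$table))
  expect_equal(nrow(m1$tuning_trace), 4)
})

test_that("prediction respects the panel contract", {
  sep <- separable_table(n_per_group = 8, seed = 10)
  model <- train_model(sep, panel_of(c("f01", "f02")), "BGLM",
                       tuning = list(lambda = 0.01), seed = 1)
  s0 <- predict_scores(model, sep$table)
  expect_true(all(s0 >= 0 & s0 <= 1))

  # duplicated rows score identically
  x <- unclass(sep$table)
  dup <- ft(x[c(1, 1, 2), ], samples = c("a", "b", "c"),
            features = colnames(x))
  sd_ <- predict_scores(model, dup)
  expect_equal(unname(sd_[1]), unname(sd_[2]))

  # columns outside the panel are ignored
  extra <- cbind(x, junk = rnorm(nrow(x)))
  expect_equal(unname(predict_scores(model, extra)), unname(s0))

  expect_error(predict_scores(model, x[, "f03", drop = FALSE]), "absent")
})

test_that("classifier evaluation matches hand-computed ROC quantities", {
  ev <- evaluate_classifier(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                            positive = "1")
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)

  ev2 <- evaluate_classifier(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0),
                             positive = "1")
  expect_equal(ev2$auc, 0.75)

  ev3 <- evaluate_classifier(rep(0.5, 6), rep(c(0, 1), 3), positive = "1")
  expect_equal(ev3$auc, 0.5)

  expect_error(evaluate_classifier(1:3, c(1, 1, 1)), "two classes")
})

test_that("AUC is symmetric under label and score inversion", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    scores <- round(runif(n), 1)          # coarse grid forces ties
    labs <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    a <- evaluate_classifier(scores, labs, positive = "1")$auc
    b <- evaluate_classifier(1 - scores, 1 - labs, positive = "1")$auc
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("combo selection follows the documented tie-break order", {
  mk <- function(auc, k, sens = 0.5, alg = "NN") {
    list(panel = panel_of(sprintf("f%02d", seq_len(k))), algorithm = alg,
         eval = structure(list(auc = auc, sensitivity = sens,
                               specificity = 0.5), class = "eval_result"))
  }
  best <- select_best_combo(list(mk(0.7, 5), mk(0.9, 10), mk(0.9, 3)))
  expect_equal(length(best$panel$features), 3)

  single <- select_best_combo(list(mk(0.6, 4)))
  expect_equal(single$eval$auc, 0.6)

  # equal AUC and size: higher sensitivity wins, then algorithm name
  best2 <- select_best_combo(list(mk(0.8, 5, sens = 0.9, alg = "NN"),
                                  mk(0.8, 5, sens = 0.7, alg = "BGLM")))
  expect_equal(best2$eval$sensitivity, 0.9)
  best3 <- select_best_combo(list(mk(0.8, 5, alg = "NN"),
                                  mk(0.8, 5, alg = "BGLM")))
  expect_equal(best3$algorithm, "BGLM")
  expect_error(select_best_combo(list()), "empty")
})

test_that("null pipelines with held-out validation have chance-level AUC", {
  # train on synthetic data from one null cohort, validate on an independent
  # null cohort: the winner's validation AUC should hover around 0.5
  aucs <- vapply(1:6, function(s) {
    co <- generate_cohort(cohort_spec(n_per_group = c(20, 20), n_features = 15,
                                      seed = 700 + s))
    held <- generate_cohort(cohort_spec(n_per_group = c(36, 36),
                                        n_features = 15, seed = 800 + s))
    res <- run_pipeline(co$table, co$labels,
                        fast_config(selection_methods = "AUC",
                                    algorithms = "BGLM", include_rf = FALSE,
                                    run_robustness = FALSE),
                        seed = s, validation = held$table,
                        validation_labels = held$labels)
    res$best$eval$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})
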