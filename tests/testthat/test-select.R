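test_that("PCA recovers degenerate structure and the SVD identity", {
  t_ <- seq(-1, 1, length.out = 20)
  x <- cbind(t_, 2 * t_, -t_)              # exactly one line in 3-space
  tab <- ft(x)
  pc <- fit_pca(tab)
  expect_equal(pc$var_share[1], 1, tolerance = 1e-12)
  expect_equal(sum(pc$var_share), 1, tolerance = 1e-12)

  set.seed(2)
  x2 <- matrix(rnorm(15 * 6), 15, 6)
  pc2 <- fit_pca(ft(x2))
  recon <- pc2$scores %*% t(pc2$loadings)
  recon <- sweep(recon, 2, pc2$center, "+")
  expect_equal(unname(recon), unname(x2), tolerance = 1e-9)

  # deterministic sign convention
  for (k in seq_len(ncol(pc2$loadings)))
    expect_gt(pc2$loadings[which.max(abs(pc2$loadings[, k])), k], 0)
})

test_that("PCA rejects constant features with scaling unless told to drop", {
  x <- cbind(rep(1, 10), rnorm(10))
  expect_error(fit_pca(ft(x), scale. = TRUE), "constant")
  pc <- fit_pca(ft(x), scale. = TRUE, drop_constant = TRUE)
  expect_equal(pc$features, "f02")
})

test_that("DAPC contributions find a planted feature and sum to one", {
  set.seed(3)
  n <- 50
  x <- matrix(rnorm(2 * n * 6), 2 * n, 6)
  x[, 1] <- x[, 1] + rep(c(0, 3), each = n)      # 3 SD shift on feature 1
  tab <- ft(x)
  lab <- labels_for(tab, rep(c("A", "B"), each = n))
  model <- fit_dapc(tab, lab)
  expect_equal(sum(model$contributions), 1, tolerance = 1e-9)
  expect_true(all(model$contributions >= 0))
  expect_equal(names(which.max(model$contributions)), "f01")
  expect_gt(model$contributions["f01"], 0.5)
})

test_that("DAPC contributions are invariant to column order and rescaling", {
  set.seed(4)
  x <- matrix(rnorm(40 * 5), 40, 5)
  x[, 3] <- x[, 3] + rep(c(0, 2), each = 20)
  tab <- ft(x)
  lab <- labels_for(tab, rep(c("A", "B"), each = 20))
  base <- fit_dapc(tab, lab)$contributions

  perm <- c(4, 1, 5, 3, 2)
  tab_p <- ft(x[, perm], features = colnames(tab)[perm])
  expect_equal(fit_dapc(tab_p, lab)$contributions[names(base)], base,
               tolerance = 1e-9)

  x_s <- x; x_s[, 2] <- 100 * x_s[, 2] - 7       # affine rescale one feature
  expect_equal(fit_dapc(ft(x_s), lab)$contributions, base, tolerance = 1e-9)
})

test_that("the contribution threshold rule selects and ranks features", {
  contrib <- c(a = 0.5, b = 0.3, c = 0.15, d = 0.05,
               e = 0, f = 0, g = 0, h = 0)
  model <- structure(list(contributions = contrib), class = "dapc_model")
  sel <- dapc_select(model, threshold = 0.02)
  expect_equal(sel$features, c("a", "b", "c", "d"))
  expect_warning(empty <- dapc_select(model, threshold = 1), "threshold")
  expect_length(empty$features, 0)
})

test_that("DAPC recovers most planted features under the 2% rule", {
  hits <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_spec(n_per_group = c(36, 36, 57),
                                      n_features = 40, planted_features = 1:10,
                                      effect_size = 1.5, seed = 600 + s))
    sel <- dapc_select(fit_dapc(co$table, co$labels), 0.02)
    sum(co$truth$planted_features %in% sel$features)
  }, numeric(1))
  expect_gte(min(hits), 8)
})

test_that("RF importance ranks a strong planted feature first, reproducibly", {
  set.seed(5)
  x <- matrix(rnorm(60 * 8), 60, 8)
  x[, 4] <- x[, 4] + rep(c(0, 3), each = 30)
  x[, 8] <- 1                                     # constant feature
  tab <- ft(x)
  lab <- labels_for(tab, rep(c("A", "B"), each = 30))
  r1 <- rf_importance(tab, lab, n_trees = 300, seed = 9)
  r2 <- rf_importance(tab, lab, n_trees = 300, seed = 9)
  expect_identical(r1$scores, r2$scores)
  expect_equal(r1$features[1], "f04")
  expect_lt(abs(r1$scores["f08"]), max(r1$scores) / 50)
})

test_that("per-feature AUC matches counting concordant pairs", {
  tab <- ft(cbind(c(1, 3, 2, 4), c(1, 2, 3, 4), c(5, 5, 5, 5)))
  lab <- labels_for(tab, c("neg", "neg", "pos", "pos"))
  r <- auc_rank(tab, lab)
  expect_equal(unname(r$scores["f01"]), 0.75)  # 3 of 4 concordant pairs
  expect_equal(unname(r$scores["f02"]), 1)     # perfect separation
  expect_equal(unname(r$scores["f03"]), 0.5)   # all tied
  # direction-free: inverted feature scores identically
  tab2 <- ft(cbind(-c(1, 2, 3, 4)))
  expect_equal(unname(auc_rank(tab2, labels_for(tab2, c("neg", "neg", "pos",
                                                        "pos")))$scores), 1)
})

test_that("candidate panels are nested top-k prefixes", {
  scores <- stats::setNames(seq(0.9, 0.1, length.out = 12),
                            sprintf("f%02d", 1:12))
  ranking <- structure(list(method = "AUC", scores = scores,
                            semantics = "test",
                            features = names(sort(-scores))),
                       class = "feature_ranking")
  panels <- candidate_panels(ranking)
  expect_length(panels, 8)
  expect_equal(vapply(panels, function(p) length(p$features), integer(1)), 3:10)
  for (p in panels)
    expect_identical(p$features, ranking$features[seq_along(p$features)])

  short <- structure(list(method = "AUC", scores = scores[1:5],
                          semantics = "test", features = names(scores)[1:5]),
                     class = "feature_ranking")
  expect_length(candidate_panels(short), 3)
  tiny <- structure(list(method = "AUC", scores = scores[1:2],
                         semantics = "test", features = names(scores)[1:2]),
                    class = "feature_ranking")
  expect_error(candidate_panels(tiny), "fewer")
})
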