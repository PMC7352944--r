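#' Two-group permutation test of the mean difference
#'
#' Clinical and omics measurements in this setting are rarely normal or
#' homoscedastic, so inference is by label permutation: the null of
#' exchangeable labels is tested with the two-sided statistic
#' `|mean(group1) - mean(group2)|`. When the number of distinct label
#' arrangements `choose(n, n1)` is at most `exhaustive_limit` every
#' arrangement is enumerated and `p` is the exact fraction of arrangements
#' with statistic greater than or equal to the observed one (the observed
#' arrangement counts, so `p > 0`). Otherwise `n_mc` random arrangements are
#' drawn and the add-one estimator `p = (b + 1) / (n_mc + 1)` is used.
#'
#' @param values numeric vector of finite measurements.
#' @param labels two-group factor/character vector aligned with `values`.
#' @param exhaustive_limit enumerate exhaustively up to this many
#'   arrangements (default 50000).
#' @param n_mc Monte-Carlo draws above the limit (default 9999).
#' @param seed seed for the Monte-Carlo path.
#' @return An object of class `perm_test`: list with `observed`, `p_value`,
#'   `n_arrangements`, `exhaustive`, `seed`.
#' @examples
#' permutation_p(1:6, rep(c("A", "B"), each = 3))$p_value # exact: 0.1
#' @export
permutation_p <- function(values, labels, exhaustive_limit = 50000,
                          n_mc = 9999, seed = 1L) {
  if (!all(is.finite(values))) stop("values must be finite")
  f <- factor(as.character(labels))
  if (nlevels(f) != 2L) stop("exactly two groups are required")
  n1 <- sum(f == levels(f)[1]); n2 <- sum(f == levels(f)[2])
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  n <- n1 + n2
  obs <- perm_stat(values, which(f == levels(f)[1]), n1, n2)
  total <- choose(n, n1)
  tol <- 1e-9 * max(1, abs(obs))
  if (total <= exhaustive_limit) {
    splits <- utils::combn(n, n1)
    stats <- apply(splits, 2, function(idx) perm_stat(values, idx, n1, n2))
    b <- sum(stats >= obs - tol)
    res <- list(observed = obs, p_value = b / total,
                n_arrangements = total, exhaustive = TRUE, seed = NA_integer_)
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    b <- 0L
    for (m in seq_len(n_mc)) {
      idx <- sample.int(n, n1)
      if (perm_stat(values, idx, n1, n2) >= obs - tol) b <- b + 1L
    }
    res <- list(observed = obs, p_value = (b + 1) / (n_mc + 1),
                n_arrangements = n_mc, exhaustive = FALSE,
                seed = as.integer(seed))
  }
  structure(res, class = "perm_test")
}

perm_stat <- function(values, idx1, n1, n2) {
  s1 <- sum(values[idx1])
  abs(s1 / n1 - (sum(values) - s1) / n2)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: observed %.4g, p = %.4g (%s, %d arrangements)\n",
              x$observed, x$p_value,
              if (x$exhaustive) "exhaustive" else "Monte Carlo",
              x$n_arrangements))
  invisible(x)
}

#' Group summaries, aggregate ratios and pairwise permutation p-values
#'
#' Produces the descriptive layer of a cohort table: per-group
#' `mean +/- SD` for every feature, per-group aggregate ratios (e.g. the
#' glycine- to taurine-conjugated bile-acid ratio, around 3 in normal bile),
#' and per-feature pairwise permutation p-values of every non-reference
#' group against the reference group.
#'
#' @param table a complete [feature_table].
#' @param labels a [cohort_labels] (2 or more groups).
#' @param ratio_specs list of `list(name =, numerator =, denominator =)`
#'   where numerator/denominator are feature-id sets; the ratio is the sum
#'   of numerator group means over the sum of denominator group means.
#' @param reference reference group name; defaults to the first level.
#' @param ... passed to [permutation_p] (e.g. `n_mc`, `seed`).
#' @return A list with data.frames `summary` (group, feature, mean, sd,
#'   formatted `mean_sd`), `ratios`, and `pairwise_p` (feature, group,
#'   p_value vs reference).
#' @export
group_summary <- function(table, labels, ratio_specs = list(),
                          reference = NULL, ...) {
  stopifnot(inherits(table, "feature_table"))
  g <- align_labels(table, labels)
  x <- unclass(table)
  if (anyNA(x)) stop("impute missing values first")
  lev <- levels(g)
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) stop("unknown reference group")
  means <- t(vapply(lev, function(l) colMeans(x[g == l, , drop = FALSE]),
                    numeric(ncol(x))))
  sds <- t(vapply(lev, function(l)
    apply(x[g == l, , drop = FALSE], 2, stats::sd), numeric(ncol(x))))
  summary_df <- data.frame(
    group = rep(lev, each = ncol(x)),
    feature = rep(colnames(x), times = length(lev)),
    mean = as.vector(t(means)), sd = as.vector(t(sds)))
  summary_df$mean_sd <- sprintf("%.3g ± %.3g", summary_df$mean, summary_df$sd)

  ratios <- do.call(rbind, lapply(ratio_specs, function(rs) {
    num <- match(rs$numerator, colnames(x))
    den <- match(rs$denominator, colnames(x))
    if (anyNA(num) || anyNA(den)) stop("unknown feature in ratio ", rs$name)
    den_sum <- rowSums(means[, den, drop = FALSE])
    if (any(den_sum <= 0))
      stop("non-positive denominator sum for ratio ", rs$name)
    data.frame(ratio = rs$name, group = lev,
               value = rowSums(means[, num, drop = FALSE]) / den_sum)
  }))

  others <- setdiff(lev, reference)
  pw <- do.call(rbind, lapply(others, function(l) {
    sel <- g %in% c(reference, l)
    p <- vapply(seq_len(ncol(x)), function(j)
      permutation_p(x[sel, j], droplevels(g[sel]), ...)$p_value, numeric(1))
    data.frame(feature = colnames(x), group = l, reference = reference,
               p_value = p)
  }))
  list(summary = summary_df, ratios = ratios, pairwise_p = pw)
}

#' Per-feature differential analysis with permutation p-values
#'
#' For every feature: log2 fold-change of group means (second level over
#' first), a Monte-Carlo permutation p-value of the absolute mean difference,
#' and Benjamini-Hochberg adjusted q-values. The volcano-plot quantities
#' `-log10(p)` vs `log2FC` follow directly. One shared set of `n_mc` label
#' permutations is used for all features (each feature's p is marginally the
#' standard add-one estimator); this is what makes 2000-feature tables cheap.
#' When a group mean is 0 a pseudocount of half the smallest positive
#' observed value is added to both means before the ratio.
#'
#' @param table a complete [feature_table].
#' @param labels two-group labels.
#' @param n_mc number of Monte-Carlo permutations (default 9999).
#' @param seed RNG seed.
#' @return data.frame with columns `feature`, `log2_fc`, `p_value`, `q_value`.
#' @export
differential_features <- function(table, labels, n_mc = 9999, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  g <- align_labels(table, labels)
  x <- unclass(table)
  if (anyNA(x)) stop("impute missing values first")
  sp <- two_group_split(g)
  if (length(sp$i1) < 2L || length(sp$i2) < 2L)
    stop("each group needs >= 2 samples")
  n <- nrow(x); n1 <- length(sp$i1); n2 <- length(sp$i2)
  m1 <- colMeans(x[sp$i1, , drop = FALSE])
  m2 <- colMeans(x[sp$i2, , drop = FALSE])
  pseudo <- function(m) {
    if (any(m1 == 0 | m2 == 0)) {
      pos <- x[x > 0]
      if (!length(pos)) stop("all-zero table: fold-change undefined")
      m + min(pos) / 2
    } else m
  }
  lfc <- log2(pseudo(m2)) - log2(pseudo(m1))
  obs <- abs(m1 - m2)
  tol <- 1e-9 * pmax(1, obs)
  colsum <- colSums(x)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  b <- integer(ncol(x))
  for (m in seq_len(n_mc)) {
    idx <- sample.int(n, n1)
    s1 <- colSums(x[idx, , drop = FALSE])
    stat <- abs(s1 / n1 - (colsum - s1) / n2)
    b <- b + (stat >= obs - tol)
  }
  p <- (b + 1) / (n_mc + 1)
  data.frame(feature = colnames(x), log2_fc = lfc, p_value = p,
             q_value = stats::p.adjust(p, method = "BH"),
             row.names = NULL)
}

#' Rank correlation with permutation p-value
#'
#' Spearman correlation of two vectors with a two-sided permutation p-value
#' obtained by shuffling `y` and comparing `|rho|`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param n_mc Monte-Carlo permutations (default 9999).
#' @param seed RNG seed.
#' @return A `perm_test` with an extra `coefficient` component (Spearman rho).
#' @export
correlate_perm <- function(x, y, n_mc = 9999, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  rho <- stats::cor(x, y, method = "spearman")
  obs <- abs(rho)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rx <- rank(x)
  b <- 0L
  for (m in seq_len(n_mc)) {
    r <- abs(stats::cor(rx, rank(sample(y))))
    if (r >= obs - 1e-12) b <- b + 1L
  }
  structure(list(observed = obs, coefficient = rho,
                 p_value = (b + 1) / (n_mc + 1),
                 n_arrangements = n_mc, exhaustive = FALSE,
                 seed = as.integer(seed)),
            class = "perm_test")
}

#' Write a differential-analysis table
#'
#' Tab-separated `feature, log2_fc, p_value, q_value`, ready for volcano
#' plotting.
#' @param diff result of [differential_features].
#' @param path file path.
#' @export
write_differential <- function(diff, path) {
  utils::write.table(diff, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
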