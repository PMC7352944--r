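# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# tiny feature table from a plain matrix
ft <- function(m, kind = "decimal", samples = NULL, features = NULL) {
  rn <- rownames(m)
  if (!is.null(samples) || is.null(rn) || anyDuplicated(rn) || any(rn == ""))
    rownames(m) <- samples %||% sprintf("s%02d", seq_len(nrow(m)))
  cn <- colnames(m)
  if (!is.null(features) || is.null(cn) || anyDuplicated(cn) || any(cn == ""))
    colnames(m) <- features %||% sprintf("f%02d", seq_len(ncol(m)))
  feature_table(m, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

labels_for <- function(tab, groups) cohort_labels(groups, rownames(tab))

# a separable two-group table: feature f01 separates groups completely,
# the rest is standard normal noise
separable_table <- function(n_per_group = 10, n_noise = 3, gap = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  x <- matrix(rnorm(n * (n_noise + 1)), n, n_noise + 1)
  x[, 1] <- x[, 1] + rep(c(0, gap), each = n_per_group)
  tab <- ft(x)
  list(table = tab,
       labels = labels_for(tab, rep(c("benign", "cancer"), each = n_per_group)))
}

# hand-built feature panel
panel_of <- function(features, method = "DAPC") {
  structure(list(features = features, method = method,
                 rule = sprintf("top-%d", length(features))),
            class = "feature_panel")
}

# hand-built BGLM model with explicit coefficients (intercept first), for
# tests that need exact control over the decision function
manual_bglm <- function(features, beta, positive = "cancer",
                        levels = c("benign", "cancer")) {
  structure(list(algorithm = "BGLM", panel = panel_of(features, "DAPC"),
                 center = stats::setNames(rep(0, length(features)), features),
                 scale = stats::setNames(rep(1, length(features)), features),
                 fit = beta, best_par = list(lambda = 0), tuning_trace = NULL,
                 positive = positive, levels = levels, seed = 0L),
            class = "trained_model")
}

# single-point tuning grids: the desk-scale configuration used for
# end-to-end tests (no cross-validation loop)
fast_config <- function(...) {
  args <- list(
    synthetic_n = 150,
    tuning = list(NN = list(size = 3, decay = 0.01),
                  BGLM = list(lambda = 0.01),
                  C5TREE = list(cp = 0.01),
                  RF = list(num_trees = 150, mtry_frac = 1)),
    rf_trees = 150, n_perm = 99, n_shuffles = 9)
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

# brute-force AUC oracle: all-pairs concordance count with half-credit ties
auc_oracle <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# brute-force exhaustive permutation oracle: enumerate group-1 index sets by
# bitmask (independent of the combn path used by the implementation)
perm_oracle <- function(values, labels) {
  f <- factor(as.character(labels))
  n <- length(values); n1 <- sum(f == levels(f)[1])
  obs <- abs(mean(values[f == levels(f)[1]]) - mean(values[f != levels(f)[1]]))
  tol <- 1e-9 * max(1, abs(obs))
  count <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (sum(bits) != n1) next
    total <- total + 1L
    stat <- abs(mean(values[bits]) - mean(values[!bits]))
    if (stat >= obs - tol) count <- count + 1L
  }
  count / total
}

# reference Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  q
}
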