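#' Estimate per-group moments of a feature table
#'
#' The seed of synthetic-data generation: per group, the sample mean vector,
#' sample SD vector (n-1 denominator) and Pearson correlation matrix.
#' Features with zero SD within a group get their correlation row/column set
#' to 0 (unit diagonal) and are flagged.
#'
#' @param table a complete [feature_table] (impute first).
#' @param labels a [cohort_labels]; every group needs >= 2 samples.
#' @return An object of class `group_moments`: named list of per-group
#'   `list(mean, sd, cor, zero_sd)`, with attributes `feature_ids` and
#'   `kind`.
#' @export
estimate_moments <- function(table, labels) {
  stopifnot(inherits(table, "feature_table"))
  g <- align_labels(table, labels)
  x <- unclass(table)
  if (anyNA(x)) stop("impute missing values first")
  out <- lapply(levels(g), function(l) {
    xi <- x[g == l, , drop = FALSE]
    if (nrow(xi) < 2L)
      stop("group ", l, " has fewer than 2 samples")
    mu <- colMeans(xi)
    sdv <- apply(xi, 2, stats::sd)
    zero <- sdv == 0
    R <- suppressWarnings(stats::cor(xi))
    R[zero, ] <- 0; R[, zero] <- 0
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    list(mean = mu, sd = sdv, cor = R, zero_sd = zero)
  })
  names(out) <- levels(g)
  structure(out, feature_ids = colnames(x), kind = ft_kind(table),
            class = "group_moments")
}

#' @export
print.group_moments <- function(x, ...) {
  cat(sprintf("group_moments: %d groups x %d features (%s)\n",
              length(x), length(attr(x, "feature_ids")), attr(x, "kind")))
  invisible(x)
}

# Repaired factor L such that L %*% t(L) approximates R after eigenvalue
# flooring at 0 (+1e-10 jitter) and diagonal renormalization to 1.
# Returns list(L, report).
repair_factor <- function(R, jitter = 1e-10) {
  e <- eigen(R, symmetric = TRUE)
  lam <- e$values
  n_clipped <- sum(lam < 0)
  lam_floor <- pmax(lam, 0) + jitter
  S <- sweep(e$vectors, 2, sqrt(lam_floor), "*")
  d <- rowSums(S^2)                       # diagonal of the repaired matrix
  scale <- ifelse(d > jitter * 10, 1 / sqrt(d), 1)
  L <- S * scale
  list(L = L,
       report = list(min_eigenvalue = min(lam), n_clipped = n_clipped,
                     clipped_mass = -sum(pmin(lam, 0)),
                     repaired = n_clipped > 0))
}

#' Generate a synthetic cohort from group moments
#'
#' Per group, draws `n_per_group` samples from a multivariate normal with
#' mean vector `mu` and covariance `D R D` (`D = diag(SD)`). Real cohorts in
#' the small-n / large-p regime (five samples, thousands of proteins) give
#' rank-deficient, often indefinite sample correlation matrices; these are
#' repaired by eigenvalue flooring at 0 (plus a 1e-10 jitter) followed by
#' diagonal renormalization, and the repair magnitude is logged in the
#' provenance. Integer mode rounds half away from zero and clamps at 0.
#' Decimal draws may be negative (moments are preserved exactly); set
#' `clamp = TRUE` to truncate at 0 instead. An optional Gaussian jitter
#' (`noise_sd`, in SD units) can emulate additional experimental noise on
#' top of the sample covariance.
#'
#' @param moments a [group_moments].
#' @param n_per_group synthetic samples per group; a single number is
#'   recycled (default 500).
#' @param mode `"decimal"` or `"integer"`; defaults to the source table kind.
#' @param seed integer seed; identical moments + seed give identical tables.
#' @param clamp clamp decimal draws at 0 (default FALSE).
#' @param noise_sd optional extra noise, as a fraction of each feature's SD.
#' @return A list of class `synthetic_cohort` with `table`, `labels` and
#'   `provenance` (moments hash, group sizes, seed, per-group PD-repair
#'   report).
#' @export
generate_synthetic <- function(moments, n_per_group = 500, mode = NULL,
                               seed = 1L, clamp = FALSE, noise_sd = 0) {
  stopifnot(inherits(moments, "group_moments"))
  feats <- attr(moments, "feature_ids")
  p <- length(feats)
  groups <- names(moments)
  n_per_group <- rep_len(as.integer(n_per_group), length(groups))
  if (any(n_per_group < 1L)) stop("n_per_group must be >= 1")
  if (is.null(mode)) mode <- attr(moments, "kind")
  mode <- match.arg(mode, c("decimal", "integer"))
  for (m in moments) {
    if (length(m$mean) != p || length(m$sd) != p ||
        !all(dim(m$cor) == c(p, p)))
      stop("dimension mismatch between moments components")
    if (any(m$sd < 0)) stop("negative SD in moments")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  blocks <- vector("list", length(groups))
  repairs <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    m <- moments[[gi]]
    rf <- repair_factor(m$cor)
    repairs[[gi]] <- rf$report
    z <- matrix(stats::rnorm(n_per_group[gi] * p), n_per_group[gi], p)
    x <- z %*% t(rf$L)                       # correlated standard normals
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow(x), p)
    x <- sweep(sweep(x, 2, m$sd, "*"), 2, m$mean, "+")
    blocks[[gi]] <- x
  }
  values <- do.call(rbind, blocks)
  if (mode == "integer") values <- round_half_away(values)
  else if (clamp) values <- pmax(values, 0)
  rownames(values) <- sprintf("SYN%05d", seq_len(nrow(values)))
  colnames(values) <- feats
  labels <- cohort_labels(rep(groups, n_per_group), rownames(values))
  names(repairs) <- groups
  prov <- list(moments_hash = moments_hash(moments),
               n_per_group = stats::setNames(n_per_group, groups),
               mode = mode, seed = as.integer(seed),
               clamp = clamp, noise_sd = noise_sd, repair = repairs)
  structure(list(table = feature_table(values, mode), labels = labels,
                 provenance = prov),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort\n")
  print(x$table)
  print(x$labels)
  invisible(x)
}

# Content hash of a moments object: stable digest of its rounded numeric
# content (no external digest dependency; collision resistance is not the
# point, traceability is).
moments_hash <- function(moments) {
  txt <- paste(vapply(moments, function(m)
    paste(format(c(m$mean, m$sd, m$cor), digits = 10), collapse = ","),
    character(1)), collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write / read group moments as structured text
#'
#' One YAML document holding, per group, the mean and SD vectors and the
#' correlation matrix (row-major), plus the feature ids and table kind.
#' @param moments a [group_moments].
#' @param path file path.
#' @export
write_moments <- function(moments, path) {
  obj <- list(feature_ids = attr(moments, "feature_ids"),
              kind = attr(moments, "kind"),
              groups = lapply(moments, function(m)
                list(mean = as.numeric(m$mean), sd = as.numeric(m$sd),
                     cor = as.numeric(t(m$cor)))))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_moments
#' @export
read_moments <- function(path) {
  obj <- yaml::read_yaml(path)
  p <- length(obj$feature_ids)
  out <- lapply(obj$groups, function(m) {
    R <- matrix(as.numeric(m$cor), p, p, byrow = TRUE,
                dimnames = list(obj$feature_ids, obj$feature_ids))
    list(mean = stats::setNames(as.numeric(m$mean), obj$feature_ids),
         sd = stats::setNames(as.numeric(m$sd), obj$feature_ids),
         cor = R, zero_sd = as.numeric(m$sd) == 0)
  })
  names(out) <- names(obj$groups)
  structure(out, feature_ids = obj$feature_ids, kind = obj$kind,
            class = "group_moments")
}
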