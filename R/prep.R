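#' Aligned 1D NMR spectra on a shared ppm axis
#'
#' @param ppm strictly monotone numeric axis.
#' @param intensities numeric matrix, one row per sample, `length(ppm)`
#'   columns, finite values.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(ppm, intensities) {
  if (is.null(dim(intensities)))
    intensities <- matrix(intensities, nrow = 1)
  d <- diff(ppm)
  if (length(ppm) < 2L || !(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotone")
  if (ncol(intensities) != length(ppm))
    stop("intensity matrix must have one column per ppm point")
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  if (all(d < 0)) { # store ascending
    ppm <- rev(ppm); intensities <- intensities[, rev(seq_along(ppm)), drop = FALSE]
  }
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("S%03d", seq_len(nrow(intensities)))
  structure(list(ppm = ppm, intensities = intensities), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d spectra, %d points, %.3f..%.3f ppm\n",
              nrow(x$intensities), length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Write spectra as text
#'
#' Tab-separated matrix with a `ppm` column followed by one column per sample.
#' @param spectra a [spectrum_set].
#' @param path file path.
#' @export
write_spectra <- function(spectra, path) {
  df <- data.frame(ppm = spectra$ppm, t(spectra$intensities),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' k-nearest-neighbour imputation of missing abundances
#'
#' Replaces each missing entry with the inverse-distance-weighted mean of the
#' k nearest samples that observed that feature. Distances are Euclidean over
#' z-scored co-observed features, normalized by the number of co-observed
#' features so samples with different missingness patterns are comparable.
#' Cohorts this size cannot afford complete-case deletion, hence imputation.
#'
#' @param table a [feature_table], possibly with `NA`s.
#' @param k neighbour count (default 5); clamped with a warning when it
#'   reaches the number of available donors.
#' @return A [feature_table] with no missing values; observed entries are
#'   untouched. A complete table is returned unchanged.
#' @export
impute_missing <- function(table, k = 5) {
  stopifnot(inherits(table, "feature_table"))
  if (k < 1) stop("k must be >= 1")
  x <- unclass(table)
  if (!anyNA(x)) return(table)
  all_missing <- colSums(!is.na(x)) == 0L
  if (any(all_missing))
    stop("feature(s) missing in all samples: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  n <- nrow(x)
  if (k >= n) {
    warning("k >= number of samples; clamped to ", n - 1L)
    k <- n - 1L
  }
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  out <- x
  for (i in which(rowSums(is.na(x)) > 0L)) {
    miss_j <- which(is.na(x[i, ]))
    # mean squared difference over co-observed features, per candidate donor
    diffs <- sweep(z, 2, z[i, ])^2
    co <- !is.na(diffs)
    co_n <- rowSums(co)
    dist2 <- ifelse(co_n > 0, rowSums(diffs, na.rm = TRUE) / co_n, Inf)
    dist2[i] <- Inf
    for (j in miss_j) {
      donors <- which(!is.na(x[, j]))
      donors <- donors[donors != i & is.finite(dist2[donors])]
      if (!length(donors))
        stop("no donor with finite distance for feature ", colnames(x)[j])
      ord <- donors[order(dist2[donors], donors)]
      nb <- ord[seq_len(min(k, length(ord)))]
      d <- sqrt(dist2[nb])
      if (any(d == 0)) {
        out[i, j] <- mean(x[nb[d == 0], j])
      } else {
        w <- 1 / d
        out[i, j] <- sum(w * x[nb, j]) / sum(w)
      }
    }
  }
  if (ft_kind(table) == "integer") out <- round_half_away(out)
  feature_table(out, ft_kind(table))
}

#' Log-transform an abundance table
#'
#' Natural-log transformation of a positive abundance table, the standard
#' variance-stabilizing step for right-skewed MS feature intensities before
#' multivariate analysis. Zeros (common in count-like proteomics tables) are
#' handled by an additive offset of half the smallest positive observed
#' value; any negative entry is an error. The result is always decimal-kind.
#'
#' @param table a [feature_table] (may contain `NA`s, which pass through).
#' @param offset additive pseudocount; `NULL` (default) uses 0 for strictly
#'   positive tables and half the minimum positive value when zeros are
#'   present.
#' @return A decimal [feature_table] of log abundances.
#' @export
log_transform <- function(table, offset = NULL) {
  stopifnot(inherits(table, "feature_table"))
  x <- unclass(table)
  obs <- x[!is.na(x)]
  if (any(obs < 0)) stop("log transform requires non-negative abundances")
  if (is.null(offset))
    offset <- if (any(obs == 0)) min(obs[obs > 0]) / 2 else 0
  if (any(obs + offset <= 0)) stop("offset leaves non-positive values")
  out <- log(x + offset)
  feature_table(out, "decimal")
}

#' Reference spectra to the 0.00-ppm standard peak
#'
#' Per sample, locates the maximum intensity inside a search window around
#' 0 ppm (the methyl signal of the TSP internal standard), shifts the axis so
#' that point sits at 0.00 ppm, and linearly re-interpolates the spectrum
#' back onto the common grid.
#'
#' @param spectra a [spectrum_set].
#' @param search_window ppm interval searched for the standard peak
#'   (default `c(-0.2, 0.2)`).
#' @return A referenced [spectrum_set] on the original grid. A flat signal in
#'   the window yields a warning and no shift for that sample.
#' @export
reference_to_standard <- function(spectra, search_window = c(-0.2, 0.2)) {
  stopifnot(inherits(spectra, "spectrum_set"))
  ppm <- spectra$ppm
  if (search_window[1] < min(ppm) || search_window[2] > max(ppm))
    stop("search window outside the ppm axis")
  win <- which(ppm >= search_window[1] & ppm <= search_window[2])
  out <- spectra$intensities
  for (i in seq_len(nrow(out))) {
    seg <- spectra$intensities[i, win]
    if (max(seg) - min(seg) <= 0) {
      warning("flat signal in reference window for sample ",
              rownames(out)[i], "; no shift applied")
      next
    }
    peak_ppm <- ppm[win[which.max(seg)]]
    if (peak_ppm != 0) {
      # shifted axis: intensity at original ppm q corresponds to q - peak_ppm
      out[i, ] <- stats::approx(ppm - peak_ppm, spectra$intensities[i, ],
                                xout = ppm, rule = 2)$y
    }
  }
  spectrum_set(ppm, out)
}

#' Bucketing configuration
#'
#' Defaults follow standard bile NMR practice: 0.01-ppm rectangular buckets
#' over 0.261--8.757 ppm, excluding the residual water region
#' (4.59--4.78 ppm) and the iohexol contrast-reagent regions.
#'
#' @param width bucket width in ppm (> 0).
#' @param region `c(low, high)` spectral region in ppm.
#' @param exclusions list of `c(low, high)` ppm intervals to drop.
#' @return An object of class `bucketing_config`.
#' @export
bucketing_config <- function(width = 0.01, region = c(0.261, 8.757),
                             exclusions = list(c(4.59, 4.78),
                                               c(1.92, 1.98), c(2.39, 2.43),
                                               c(3.39, 3.71), c(3.76, 4.18))) {
  if (width <= 0) stop("width must be > 0")
  if (region[1] >= region[2]) stop("region low must be < high")
  keep <- vapply(exclusions, function(e) e[1] < region[2] && e[2] > region[1],
                 logical(1))
  if (length(exclusions) && !all(keep)) {
    warning("exclusion region(s) outside the spectral region ignored")
    exclusions <- exclusions[keep]
  }
  structure(list(width = width, region = region, exclusions = exclusions),
            class = "bucketing_config")
}

# trapezoidal integral of one spectrum row over [a, b] on grid ppm,
# linearly interpolating the endpoints so contiguous intervals telescope
trapz_interval <- function(ppm, y, a, b) {
  if (b <= a) return(0)
  inner <- which(ppm > a & ppm < b)
  xa <- stats::approx(ppm, y, xout = a, rule = 2)$y
  xb <- stats::approx(ppm, y, xout = b, rule = 2)$y
  xs <- c(a, ppm[inner], b)
  ys <- c(xa, y[inner], xb)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Bucket spectra into fixed-width rectangular bins
#'
#' Buckets are half-open intervals `[low + i*width, low + (i+1)*width)`
#' anchored at the region's low edge; the final bucket is truncated at the
#' high edge and kept. The bucket value is the trapezoidal integral of the
#' intensity over the interval. Buckets overlapping any exclusion region are
#' dropped (any-overlap rule); their integrals are retained in the result's
#' `dropped` component so mass is fully accounted for.
#'
#' @param spectra a [spectrum_set] whose axis covers the requested region.
#' @param cfg a [bucketing_config].
#' @return An object of class `bucket_table`: list with `intervals`
#'   (two-column matrix of bucket bounds), `values` (samples x buckets
#'   integral matrix), `normalization` (`"raw"`), `dilution` (per-sample
#'   cumulative relative-dilution estimate, 1 until normalization), and
#'   `dropped` (intervals and integrals of excluded buckets).
#' @export
bucket_spectra <- function(spectra, cfg = bucketing_config()) {
  stopifnot(inherits(spectra, "spectrum_set"), inherits(cfg, "bucketing_config"))
  ppm <- spectra$ppm
  if (cfg$region[1] < min(ppm) || cfg$region[2] > max(ppm))
    stop("spectral region outside the ppm axis")
  lo <- cfg$region[1]; hi <- cfg$region[2]; w <- cfg$width
  n_buckets <- ceiling((hi - lo) / w - 1e-9)
  starts <- lo + (seq_len(n_buckets) - 1) * w
  ends <- pmin(starts + w, hi)
  overlaps_excl <- vapply(seq_len(n_buckets), function(i) {
    any(vapply(cfg$exclusions,
               function(e) starts[i] < e[2] && ends[i] > e[1], logical(1)))
  }, logical(1))
  vals <- matrix(0, nrow(spectra$intensities), n_buckets)
  for (s in seq_len(nrow(vals)))
    vals[s, ] <- vapply(seq_len(n_buckets), function(i)
      trapz_interval(ppm, spectra$intensities[s, ], starts[i], ends[i]),
      numeric(1))
  mids <- (starts + ends) / 2
  keep <- !overlaps_excl
  kept_vals <- vals[, keep, drop = FALSE]
  rownames(kept_vals) <- rownames(spectra$intensities)
  colnames(kept_vals) <- sprintf("%.4f", mids[keep])
  structure(list(
    intervals = cbind(low = starts[keep], high = ends[keep]),
    values = kept_vals,
    normalization = "raw",
    dilution = stats::setNames(rep(1, nrow(kept_vals)), rownames(kept_vals)),
    pqn_factor = NULL,
    dropped = list(intervals = cbind(low = starts[!keep], high = ends[!keep]),
                   values = vals[, !keep, drop = FALSE])),
    class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("bucket_table: %d samples x %d buckets (%s), %d buckets dropped\n",
              nrow(x$values), ncol(x$values), x$normalization,
              ncol(x$dropped$values)))
  invisible(x)
}

#' Normalize a bucket table
#'
#' `total_area` divides each sample's row by its total so rows sum to 1;
#' `pqn` (probabilistic quotient normalization) divides each row by the
#' median of its bucketwise quotients against a reference row (default: the
#' bucketwise median across samples) and records that quotient as the
#' sample's dilution factor. The canonical chain is total-area first, then
#' PQN. Buckets where the reference is 0 are excluded from the quotient
#' median. The `dilution` component accumulates a relative dilution estimate
#' across normalizations: total-area contributes `row_total / median(row
#' totals)`, PQN contributes its quotient factor; the estimate is therefore
#' defined up to the scale of the reference.
#'
#' @param buckets a [bucket_table] whose rows all have positive totals.
#' @param method `"total_area"` or `"pqn"`.
#' @param reference `"median"` or a numeric vector of reference bucket values
#'   (for PQN).
#' @return The normalized [bucket_table]; PQN additionally fills `pqn_factor`.
#' @export
normalize_buckets <- function(buckets, method = c("total_area", "pqn"),
                              reference = "median") {
  stopifnot(inherits(buckets, "bucket_table"))
  method <- match.arg(method)
  v <- buckets$values
  totals <- rowSums(v)
  if (any(totals <= 0))
    stop("non-positive total for sample(s): ",
         paste(rownames(v)[totals <= 0], collapse = ", "))
  if (method == "total_area") {
    buckets$values <- v / totals
    buckets$dilution <- buckets$dilution * totals / stats::median(totals)
    buckets$normalization <- "total_area"
  } else {
    if (identical(reference, "median")) {
      ref <- apply(v, 2, stats::median)
    } else {
      ref <- as.numeric(reference)
      if (length(ref) != ncol(v)) stop("reference length must match bucket count")
    }
    usable <- ref != 0
    if (!any(usable)) stop("reference has no non-zero buckets")
    q <- sweep(v[, usable, drop = FALSE], 2, ref[usable], "/")
    f <- apply(q, 1, stats::median)
    buckets$values <- v / f
    buckets$pqn_factor <- stats::setNames(f, rownames(v))
    buckets$dilution <- buckets$dilution * f
    buckets$normalization <- "pqn"
  }
  buckets
}

#' Write a bucket table as text
#'
#' Tab-separated, first column the sample id, one column per kept bucket with
#' the interval midpoint (4 decimals) as header.
#' @param buckets a [bucket_table].
#' @param path file path.
#' @export
write_bucket_table <- function(buckets, path) {
  df <- data.frame(sample_id = rownames(buckets$values),
                   buckets$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
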