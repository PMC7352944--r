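#' Specification of a synthetic cohort with planted ground truth
#'
#' Describes a cohort generator that emulates bile omics feature tables:
#' log-normal baseline abundances, block-correlated features, a subset of
#' features carrying a planted group effect, and MCAR missingness. The
#' defaults mirror the study conditions the package targets: a
#' lipidomics-like table of 162 continuous features over groups of
#' 36 benign / 36 CCA / 57 PDAC samples.
#'
#' Effects are planted on the latent Gaussian (log) scale: in every
#' non-reference group the latent mean of each planted feature is shifted by
#' `effect_size` within-group standard deviations. Correlation blocks impose
#' the given intra-block correlation on the latent Gaussian via its Cholesky
#' factor (a Gaussian copula on the observed scale).
#'
#' @param n_per_group integer vector of group sizes (>= 2 each); the first
#'   group is the reference (no planted shift).
#' @param n_features number of features.
#' @param planted_features integer indices of features carrying the effect.
#' @param effect_size latent-scale shift in within-group SD units (>= 0).
#' @param correlation_blocks list of `list(features = <indices>, rho = <cor>)`
#'   with disjoint index sets and `0 <= rho < 1`.
#' @param base_mean,base_sd location and scale of the latent Gaussian.
#' @param missing_rate MCAR missingness fraction in `[0, 1)`.
#' @param mode `"decimal"` (exp of the latent Gaussian) or `"integer"`
#'   (additionally rounded half away from zero and clamped at 0).
#' @param group_names optional group names; defaults to `benign`, `CCA`,
#'   `PDAC`, then `G4`, `G5`, ...
#' @param seed integer seed making generation reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(36, 36, 57), n_features = 162,
                        planted_features = integer(), effect_size = 0,
                        correlation_blocks = list(),
                        base_mean = 0, base_sd = 1,
                        missing_rate = 0, mode = c("decimal", "integer"),
                        group_names = NULL, seed = 1L) {
  mode <- match.arg(mode)
  n_per_group <- as.integer(n_per_group)
  if (any(n_per_group < 2L)) stop("each group needs >= 2 samples")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (effect_size > 0 && length(planted_features) == 0L)
    stop("effect_size > 0 requires at least one planted feature")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  planted_features <- as.integer(planted_features)
  if (length(planted_features) &&
      (min(planted_features) < 1L || max(planted_features) > n_features))
    stop("planted_features outside the feature index range")
  all_block <- unlist(lapply(correlation_blocks, `[[`, "features"))
  if (anyDuplicated(all_block)) stop("correlation block index sets must be disjoint")
  if (length(all_block) && (min(all_block) < 1 || max(all_block) > n_features))
    stop("correlation block indices outside the feature index range")
  for (b in correlation_blocks)
    if (b$rho < 0 || b$rho >= 1) stop("block correlation must be in [0, 1)")
  if (is.null(group_names)) {
    group_names <- c("benign", "CCA", "PDAC", paste0("G", seq_len(26) + 3L))
    group_names <- group_names[seq_along(n_per_group)]
  }
  if (length(group_names) != length(n_per_group))
    stop("group_names length must match n_per_group")
  structure(list(n_per_group = n_per_group, n_features = as.integer(n_features),
                 planted_features = planted_features, effect_size = effect_size,
                 correlation_blocks = correlation_blocks,
                 base_mean = base_mean, base_sd = base_sd,
                 missing_rate = missing_rate, mode = mode,
                 group_names = group_names, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Draw an n x p latent standard-normal matrix with the spec's block
# correlations imposed (Cholesky per block on iid normals).
latent_draw <- function(n, spec) {
  z <- matrix(stats::rnorm(n * spec$n_features), n, spec$n_features)
  for (b in spec$correlation_blocks) {
    idx <- b$features
    k <- length(idx)
    if (k < 2L || b$rho == 0) next
    R <- matrix(b$rho, k, k); diag(R) <- 1
    z[, idx] <- z[, idx, drop = FALSE] %*% chol(R)
  }
  z
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param spec a [cohort_spec].
#' @return A list with components `table` (a [feature_table]), `labels`
#'   (a [cohort_labels]) and `truth` (the planted ground-truth record:
#'   planted feature ids, effect size, latent group means, the spec itself).
#'   Identical spec (including its seed) gives bitwise-identical output.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_group = c(5, 5), n_features = 8,
#'                                       planted_features = 1:2,
#'                                       effect_size = 2, seed = 7))
#' dim(cohort$table)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- sum(spec$n_per_group)
  p <- spec$n_features
  withr_seed <- spec$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)

  z <- latent_draw(n, spec)
  latent <- spec$base_mean + spec$base_sd * z
  group <- rep(seq_along(spec$n_per_group), spec$n_per_group)
  if (length(spec$planted_features) && spec$effect_size > 0) {
    shift <- spec$effect_size * spec$base_sd
    rows <- group != 1L
    latent[rows, spec$planted_features] <-
      latent[rows, spec$planted_features, drop = FALSE] + shift
  }
  values <- exp(latent)
  if (spec$mode == "integer") values <- round_half_away(values)
  if (spec$missing_rate > 0) {
    miss <- stats::runif(n * p) < spec$missing_rate
    values[matrix(miss, n, p)] <- NA_real_
  }
  sample_ids <- sprintf("S%03d", seq_len(n))
  feature_ids <- sprintf("F%03d", seq_len(p))
  dimnames(values) <- list(sample_ids, feature_ids)
  labels <- cohort_labels(spec$group_names[group], sample_ids)
  truth <- list(planted_features = feature_ids[spec$planted_features],
                planted_index = spec$planted_features,
                effect_size = spec$effect_size,
                spec = spec)
  list(table = feature_table(values, spec$mode), labels = labels, truth = truth)
}

# round half away from zero, clamped at 0 (values are positive pre-clamp,
# the clamp guards the integer-kind invariant)
round_half_away <- function(x) pmax(floor(abs(x) + 0.5) * sign(x), 0)

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Specification of simulated 1D NMR spectra
#'
#' Toy bile spectra on a shared ppm grid: each spectrum is a per-sample
#' dilution factor times a sum of Lorentzian peaks (the 0.00-ppm reference
#' standard peak among them, optionally displaced to emulate mis-referencing),
#' plus spurious rectangular artifact bumps (emulating residual water and
#' contrast-reagent signal, not scaled by dilution) and Gaussian noise.
#'
#' @param ppm_range numeric length-2, low and high ppm of the grid.
#' @param step grid step in ppm (> 0).
#' @param peaks data.frame with columns `center`, `height`, `hwhm`
#'   (Lorentzian half-width at half-maximum, ppm); centers must lie on the
#'   grid range. Peak shape is height-normalized: maximum equals `height`.
#' @param dilution_factors positive per-sample multipliers; recycled/cropped
#'   to the number of samples requested at generation time.
#' @param artifact_regions list of `c(low, high)` ppm intervals receiving a
#'   spurious rectangular bump of random height per sample.
#' @param artifact_height scale of the artifact bumps.
#' @param noise_sd Gaussian noise SD.
#' @param reference_peak_offset ppm displacement of the reference standard
#'   peak away from 0.00.
#' @param reference_peak_height height of the reference peak.
#' @param seed integer seed.
#' @return An object of class `spectrum_spec`.
#' @export
spectrum_spec <- function(ppm_range = c(-0.5, 9.5), step = 0.002,
                          peaks, dilution_factors = 1,
                          artifact_regions = list(), artifact_height = 1,
                          noise_sd = 0, reference_peak_offset = 0,
                          reference_peak_height = 5, seed = 1L) {
  if (step <= 0) stop("step must be > 0")
  if (missing(peaks) || is.null(peaks) || nrow(peaks) == 0L)
    stop("at least one peak is required")
  stopifnot(all(c("center", "height", "hwhm") %in% names(peaks)))
  if (any(peaks$center < ppm_range[1]) || any(peaks$center > ppm_range[2]))
    stop("peak centers must lie within the ppm grid")
  if (any(dilution_factors <= 0)) stop("dilution factors must be > 0")
  structure(list(ppm_range = ppm_range, step = step, peaks = peaks,
                 dilution_factors = dilution_factors,
                 artifact_regions = artifact_regions,
                 artifact_height = artifact_height,
                 noise_sd = noise_sd,
                 reference_peak_offset = reference_peak_offset,
                 reference_peak_height = reference_peak_height,
                 seed = as.integer(seed)),
            class = "spectrum_spec")
}

lorentzian <- function(ppm, center, height, hwhm) {
  height * hwhm^2 / ((ppm - center)^2 + hwhm^2)
}

#' Generate simulated spectra
#'
#' @param spec a [spectrum_spec].
#' @param n_samples number of spectra.
#' @return A list with `spectra` (a [spectrum_set]) and `dilution` (the true
#'   per-sample dilution factors). Deterministic under a fixed spec seed.
#' @export
generate_spectra <- function(spec, n_samples) {
  stopifnot(inherits(spec, "spectrum_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  ppm <- seq(spec$ppm_range[1], spec$ppm_range[2], by = spec$step)
  base <- rep(0, length(ppm))
  # a non-zero reference_peak_offset emulates a calibration error, which
  # displaces the entire spectrum (every peak), not just the standard
  off <- spec$reference_peak_offset
  for (i in seq_len(nrow(spec$peaks)))
    base <- base + lorentzian(ppm, spec$peaks$center[i] + off,
                              spec$peaks$height[i], spec$peaks$hwhm[i])
  # the reference standard peak, nominally at 0.00 ppm
  base <- base + lorentzian(ppm, off, spec$reference_peak_height,
                            2 * spec$step)
  d <- rep_len(spec$dilution_factors, n_samples)
  intens <- outer(d, base)
  for (reg in spec$artifact_regions) {
    inside <- ppm >= reg[1] & ppm <= reg[2]
    if (!any(inside)) next
    h <- stats::runif(n_samples, 0.5, 1.5) * spec$artifact_height
    intens[, inside] <- intens[, inside, drop = FALSE] + h
  }
  if (spec$noise_sd > 0)
    intens <- intens + matrix(stats::rnorm(length(intens), sd = spec$noise_sd),
                              nrow = n_samples)
  rownames(intens) <- sprintf("S%03d", seq_len(n_samples))
  list(spectra = spectrum_set(ppm, intens), dilution = d)
}
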