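#' Sample-by-feature abundance table
#'
#' The universal data currency of the pipeline: a numeric matrix with one row
#' per sample and one column per feature, plus a declared kind. Missing values
#' are stored as `NA`. Integer-kind tables hold non-negative whole numbers
#' (counts, as in spectral-count proteomics); decimal-kind tables hold
#' continuous abundances (as in MS lipidomics or NMR bucket intensities).
#'
#' @param values numeric matrix, samples in rows, features in columns. Must
#'   have unique, non-empty row and column names (sample and feature ids).
#' @param kind `"decimal"` or `"integer"`.
#' @return An object of class `feature_table`: the matrix with a `kind`
#'   attribute.
#' @examples
#' m <- matrix(rexp(12), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
#' ft <- feature_table(m)
#' dim(ft)
#' @export
feature_table <- function(values, kind = c("decimal", "integer")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids")
  if (kind == "integer") {
    obs <- values[!is.na(values)]
    if (any(obs < 0) || any(obs != round(obs)))
      stop("integer-kind table must contain only non-negative whole numbers where observed")
  }
  structure(values, kind = kind, class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%s, %d missing)\n",
              nrow(x), ncol(x), attr(x, "kind"), sum(is.na(x))))
  invisible(x)
}

ft_kind <- function(x) attr(x, "kind") %||% "decimal"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample-to-group labels
#'
#' @param groups a factor or character vector of group names, one per sample.
#' @param sample_ids sample identifiers; defaults to `names(groups)`.
#' @return A named factor of class `cohort_labels`.
#' @export
cohort_labels <- function(groups, sample_ids = names(groups)) {
  if (is.null(sample_ids)) stop("sample ids are required")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in labels")
  # group order is first appearance (or the factor's own levels), never a
  # locale-dependent sort: the first group is the reference downstream
  lev <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  g <- factor(as.character(groups), levels = lev)
  if (anyNA(g)) stop("labels may not contain NA groups")
  names(g) <- sample_ids
  class(g) <- c("cohort_labels", "factor")
  g
}

#' @export
print.cohort_labels <- function(x, ...) {
  print(table(unclass(x)))
  invisible(x)
}

# Align a labels vector to a table's samples, failing loudly on mismatch.
align_labels <- function(table, labels) {
  if (is.null(names(labels)))
    stop("labels must be named by sample id")
  missing <- setdiff(rownames(table), names(labels))
  if (length(missing))
    stop("samples without labels: ", paste(utils::head(missing, 5), collapse = ", "))
  lev <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
  out <- factor(as.character(labels[rownames(table)]), levels = lev)
  names(out) <- rownames(table)
  out
}

# Two-group helper: returns list(g1, g2 index vectors, levels) or errors.
two_group_split <- function(labels) {
  lev0 <- if (is.factor(labels)) levels(droplevels(labels))
          else unique(as.character(labels))
  f <- factor(as.character(labels), levels = lev0)
  lev <- levels(f)
  if (length(lev) != 2L)
    stop("exactly two groups are required, got ", length(lev))
  list(i1 = which(f == lev[1L]), i2 = which(f == lev[2L]), levels = lev)
}

#' Read / write feature tables
#'
#' Tables are stored as tab-separated text: first column the sample id,
#' remaining columns one per feature with feature ids in the header.
#'
#' @param x a [feature_table].
#' @param path file path.
#' @param kind declared kind when reading.
#' @return `read_feature_table` returns a [feature_table];
#'   `write_feature_table` returns `path` invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, kind = c("decimal", "integer")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  feature_table(m, match.arg(kind))
}

#' Read / write cohort labels
#'
#' Two-column tab-separated text: `sample_id`, `group`.
#' @param labels a [cohort_labels].
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), group = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cohort_labels(df$group, df$sample_id)
}
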