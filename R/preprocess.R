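#' Fit population z-score statistics
#'
#' Per-column mean and population standard deviation (divide-by-N, not the
#' sample N-1 form) over the rows supplied. Statistics are fit once and
#' applied with [zscore_apply()], so the same scaling can be reused on new
#' rows (e.g. the test fold of a leakage-free cross-validation).
#'
#' @param X numeric matrix, p x n, p >= 1. `NA` cells are excluded from the
#'   statistics column-wise.
#' @return Object of class `zscore_stats`: list with `mean` and `sd`
#'   (population), each of length n.
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("cannot fit z-score statistics on an empty matrix")
  mu <- colMeans(X, na.rm = TRUE)
  sdev <- sqrt(colMeans(sweep(X, 2L, mu, "-")^2, na.rm = TRUE))
  structure(list(mean = mu, sd = sdev, n = ncol(X)), class = "zscore_stats")
}

#' Apply (or invert) a z-score transform
#'
#' `zscore_apply()` maps each entry to `(x - mean_j) / sd_j`. Columns with
#' zero population standard deviation (constant features) map to all-zeros
#' rather than NaN: a constant feature carries no information, and erroring
#' would block otherwise valid datasets. `zscore_invert()` undoes the
#' transform for columns with positive sd.
#'
#' @param X numeric matrix or vector with n columns/components.
#' @param stats a `zscore_stats` from [zscore_fit()].
#' @return Same shape as `X`.
#' @export
zscore_apply <- function(X, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  vec <- !is.matrix(X)
  X <- if (vec) rbind(as.numeric(X)) else as.matrix(X)
  if (ncol(X) != stats$n) stop("matrix has ", ncol(X), " columns, stats expect ", stats$n)
  sd_safe <- ifelse(stats$sd > 0, stats$sd, 1)
  Z <- sweep(sweep(X, 2L, stats$mean, "-"), 2L, sd_safe, "/")
  Z[, stats$sd == 0] <- 0
  if (vec) drop(Z) else Z
}

#' @rdname zscore_apply
#' @export
zscore_invert <- function(X, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  vec <- !is.matrix(X)
  X <- if (vec) rbind(as.numeric(X)) else as.matrix(X)
  if (ncol(X) != stats$n) stop("matrix has ", ncol(X), " columns, stats expect ", stats$n)
  Z <- sweep(sweep(X, 2L, stats$sd, "*"), 2L, stats$mean, "+")
  if (vec) drop(Z) else Z
}

#' Wilson editing (edited nearest neighbour)
#'
#' Identifies atypical patterns, primarily those in the overlap region
#' between classes: each pattern's class is estimated by the plurality
#' label of its k nearest neighbours (Euclidean distance, the pattern
#' itself excluded), and patterns whose own label disagrees are removed.
#' This is the classic single simultaneous pass: every pattern is judged
#' against the original set and the failures are removed together, so the
#' result does not depend on a removal order.
#'
#' Tie rules (deterministic for a fixed row order): distance ties at the
#' k-th neighbour prefer the lower row index; when the neighbour labels
#' have no unique plurality the pattern is conservatively kept.
#'
#' @param data a [fundamental_set()] with numeric, complete features.
#' @param k number of neighbours, default 3.
#' @return Object of class `edit_result`: list with `kept_indices`,
#'   `removed_indices` (disjoint, union = all rows), and
#'   `removed_per_class` (length m, in label-map order).
#' @export
wilson_edit <- function(data, k = 3) {
  stopifnot(inherits(data, "fundamental_set"))
  p <- nrow(data$X)
  if (p <= k) stop("need more than k = ", k, " patterns, got ", p)
  if (anyNA(data$X)) stop("Wilson editing requires complete numeric features")
  D <- as.matrix(stats::dist(data$X))
  removed <- logical(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    # stable order: ties at the k-th neighbour resolved toward lower index
    nb <- others[order(D[i, others], others)][seq_len(k)]
    counts <- tabulate(data$labels[nb], data$m)
    winners <- which(counts == max(counts))
    if (length(winners) == 1L && winners != data$labels[i]) removed[i] <- TRUE
  }
  removed_idx <- which(removed)
  structure(
    list(kept_indices = which(!removed), removed_indices = removed_idx,
         removed_per_class = tabulate(data$labels[removed_idx], data$m)),
    class = "edit_result"
  )
}

#' Class-conditional imputation of missing values
#'
#' Replaces each missing cell by a statistic of the observed values of the
#' same attribute within the same class: the class mean for continuous
#' attributes and the class mode for categorical ones. Observed cells are
#' never altered. Mode ties resolve to the smallest coded value.
#'
#' @param X numeric matrix with `NA` marking missing cells (categorical
#'   attributes integer-coded, as produced by [read_dataset()]).
#' @param labels integer class indices in `1..m`, one per row.
#' @param schema an [attribute_schema()] declaring which attributes are
#'   continuous and which categorical.
#' @return Complete numeric matrix of the same shape.
#' @export
impute_class_conditional <- function(X, labels, schema) {
  X <- as.matrix(X)
  stopifnot(inherits(schema, "attribute_schema"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) stop("one label per row required")
  if (length(schema$kinds) != ncol(X)) {
    stop("schema declares ", length(schema$kinds), " attributes, matrix has ", ncol(X))
  }
  for (j in seq_len(ncol(X))) {
    miss <- which(is.na(X[, j]))
    for (i in miss) {
      k <- labels[i]
      obs <- X[labels == k & !is.na(X[, j]), j]
      if (length(obs) == 0L) {
        stop("no observed values for class ", k, ", attribute ", j,
             ": cannot impute")
      }
      X[i, j] <- if (schema$kinds[j] == "categorical") mode_value(obs) else mean(obs)
    }
  }
  X
}

mode_value <- function(x) {
  tab <- table(x)
  vals <- as.numeric(names(tab))
  cand <- vals[tab == max(tab)]
  min(cand)
}

#' Drop rows with missing values
#'
#' Removes every row containing at least one missing cell, preserving the
#' order of the survivors. This is the conditioning used when a dataset has
#' few enough incomplete records that deleting them is affordable.
#'
#' @param X numeric matrix with `NA` marking missing cells.
#' @param labels vector of per-row labels (any coding), subset alongside.
#' @return List with `X`, `labels`, and `dropped_count`. Warns (but does
#'   not error) when every row is dropped.
#' @export
drop_missing_rows <- function(X, labels) {
  X <- as.matrix(X)
  keep <- !apply(X, 1L, anyNA)
  if (!any(keep)) warning("all rows contained missing values; result is empty")
  list(X = X[keep, , drop = FALSE], labels = labels[keep],
       dropped_count = sum(!keep))
}

#' Attribute schema for a tabular dataset
#'
#' Declares, per feature column, whether the attribute is continuous or
#' categorical, plus the class column and missing marker used when reading
#' files. Drives [impute_class_conditional()] and [read_dataset()].
#'
#' @param kinds character vector, one of "continuous"/"categorical" per
#'   feature column.
#' @param class_col class column in the source file: name or 1-based index.
#' @param missing_marker string marking a missing cell, default `"?"` (the
#'   UCI convention).
#' @return Object of class `attribute_schema`.
#' @export
attribute_schema <- function(kinds, class_col = NULL, missing_marker = "?") {
  kinds <- as.character(kinds)
  bad <- setdiff(unique(kinds), c("continuous", "categorical"))
  if (length(bad) > 0L) {
    stop("attribute kinds must be 'continuous' or 'categorical', got: ",
         paste(bad, collapse = ", "))
  }
  structure(list(kinds = kinds, class_col = class_col,
                 missing_marker = missing_marker),
            class = "attribute_schema")
}
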