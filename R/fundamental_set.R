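#' Fundamental set of labeled patterns
#'
#' The training container used by every classifier in the package: a matrix
#' of p input patterns (rows) with n real-valued features, plus an integer
#' class index per row. Original labels (factor levels, strings, arbitrary
#' integers) are preserved in a label map; internally classes are indices
#' `1..m`.
#'
#' @param X numeric matrix (p x n) or an object coercible to one; one row
#'   per pattern. `NA` entries are allowed (they mark missing values and are
#'   resolved by the preprocessing functions before model fitting).
#' @param labels vector of length p with one class label per row; any atomic
#'   type. Level order of the label map follows `sort(unique(labels))`.
#' @param label_map optional character vector fixing the label-to-index
#'   mapping (index k has original label `label_map[k]`); labels not in the
#'   map are an error. Used to keep maps stable across data subsets.
#'
#' @return An object of class `fundamental_set`: a list with elements `X`
#'   (numeric matrix), `labels` (integer vector in `1..m`), `m` (number of
#'   classes), and `label_map` (character vector of length m).
#' @examples
#' fs <- fundamental_set(rbind(c(1, 1), c(3, 1), c(-1, -1)), c("a", "a", "b"))
#' fs$m
#' @export
fundamental_set <- function(X, labels, label_map = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 1L) stop("fundamental set must contain at least one pattern")
  if (length(labels) != nrow(X)) {
    stop("number of labels (", length(labels), ") does not match number of rows (",
         nrow(X), ")")
  }
  if (anyNA(labels)) stop("class labels must not be missing")
  lab_chr <- as.character(labels)
  if (is.null(label_map)) {
    label_map <- as.character(sort(unique(labels)))
  } else {
    label_map <- as.character(label_map)
    if (anyDuplicated(label_map)) stop("label_map must not contain duplicates")
    if (!all(lab_chr %in% label_map)) {
      stop("labels not covered by label_map: ",
           paste(setdiff(lab_chr, label_map), collapse = ", "))
    }
  }
  idx <- match(lab_chr, label_map)
  structure(
    list(X = X, labels = as.integer(idx), m = length(label_map),
         label_map = label_map),
    class = "fundamental_set"
  )
}

#' @export
print.fundamental_set <- function(x, ...) {
  cat("Fundamental set: ", nrow(x$X), " patterns, ", ncol(x$X),
      " features, ", x$m, " classes\n", sep = "")
  cat("Class sizes:", paste(sprintf("%s=%d", x$label_map,
                                    tabulate(x$labels, x$m)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.fundamental_set` <- function(x, i) {
  fundamental_set(x$X[i, , drop = FALSE], x$label_map[x$labels[i]],
                  label_map = x$label_map)
}

# Original labels for internal class indices, preserving the input type as
# closely as a character map allows.
decode_labels <- function(fs_or_map, idx) {
  map <- if (is.character(fs_or_map)) fs_or_map else fs_or_map$label_map
  map[idx]
}

assert_pattern_length <- function(x, n, what = "input pattern") {
  if (length(x) != n) {
    stop(what, " has length ", length(x), ", expected ", n)
  }
}
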