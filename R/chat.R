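#' Centroid of a pattern set
#'
#' The mean vector of a set of input patterns: component j is the arithmetic
#' average of column j. Used as the new coordinate origin by CHAT and
#' CHAT-OHM.
#'
#' @param X numeric matrix, p x n, p >= 1.
#' @return Numeric vector of length n.
#' @export
compute_centroid <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("cannot compute the centroid of an empty set")
  colMeans(X)
}

#' Translate patterns to a new origin
#'
#' Subtracts a centroid component-wise from a vector or from every row of a
#' matrix, moving the coordinate origin to the centroid. Translating a set
#' by its own centroid gives columns with zero mean.
#'
#' @param X numeric vector of length n or matrix with n columns.
#' @param centroid numeric vector of length n.
#' @return Same shape as `X`, translated.
#' @export
translate <- function(X, centroid) {
  centroid <- as.numeric(centroid)
  if (is.matrix(X)) {
    if (ncol(X) != length(centroid)) {
      stop("centroid length ", length(centroid), " does not match ", ncol(X),
           " columns")
    }
    return(sweep(X, 2L, centroid, "-"))
  }
  x <- as.numeric(X)
  assert_pattern_length(x, length(centroid))
  x - centroid
}

#' Fit a CHAT (or CHA) classifier
#'
#' The hybrid associative classifier combines the learning phase of the
#' Linear Associator with the recall phase of the Lernmatrix. Class k is
#' coded as a one-hot output of length m; with axis translation enabled the
#' coordinate origin is first moved to the centroid of the training inputs
#' (CHAT), without it the model is the original CHA. Because the outputs
#' are class-one-hot, row k of the learned memory equals the sum of the
#' translated training patterns of class k.
#'
#' @param data a [fundamental_set()].
#' @param translate_axes move the origin to the training centroid before
#'   learning (default `TRUE`; `FALSE` gives CHA).
#' @return Object of class `chat_model`: list with `centroid` (length n;
#'   all zeros for CHA), `weights` (m x n), `label_map`, `n`, `m`.
#' @seealso [chat_predict()], [chat_ohm_fit()]
#' @examples
#' fs <- fundamental_set(rbind(c(1, 1), c(3, 1), c(-1, -1), c(-3, -1)),
#'                       c(0, 0, 1, 1))
#' fit <- chat_fit(fs)
#' chat_predict(fit, c(2, 1))
#' @export
chat_fit <- function(data, translate_axes = TRUE) {
  stopifnot(inherits(data, "fundamental_set"))
  if (anyNA(data$X)) stop("training data contain missing values; impute or drop them first")
  n <- ncol(data$X)
  centroid <- if (translate_axes) compute_centroid(data$X) else rep(0, n)
  Xhat <- translate(data$X, centroid)
  # Linear-Associator learning with class one-hot outputs: the outer-product
  # sum collapses to per-class column sums of the translated patterns.
  W <- matrix(0, data$m, n)
  for (k in seq_len(data$m)) {
    W[k, ] <- colSums(Xhat[data$labels == k, , drop = FALSE])
  }
  structure(list(centroid = centroid, weights = W, label_map = data$label_map,
                 n = n, m = data$m),
            class = "chat_model")
}

#' Classify with a CHAT model
#'
#' Translates the query by the stored centroid, applies Lernmatrix recall
#' (arg-max of `weights %*% x_hat`), and returns the label of the maximal
#' class. When several scores are within relative tolerance 1e-9 of the
#' maximum the smallest class index wins; the full binary recall vector is
#' available via `chat_scores()`.
#'
#' @param model a `chat_model` from [chat_fit()].
#' @param x query: numeric vector of length n, or a matrix of queries (one
#'   per row).
#' @return Predicted label(s), in the original label coding.
#' @export
chat_predict <- function(model, x) {
  stopifnot(inherits(model, "chat_model"))
  Xq <- if (is.matrix(x)) x else rbind(as.numeric(x))
  if (ncol(Xq) != model$n) stop("query has ", ncol(Xq), " features, expected ", model$n)
  U <- model$weights %*% t(translate(Xq, model$centroid))  # m x nq
  idx <- apply(U, 2L, which_max_tol)
  out <- decode_labels(model$label_map, idx)
  if (is.matrix(x)) out else out[[1L]]
}

#' Raw class scores and recall vector of a CHAT model
#'
#' Exposes the Lernmatrix recall underlying [chat_predict()]: the class
#' scores and the binary vector flagging every score in the arg-max set
#' (within relative tolerance 1e-9).
#'
#' @inheritParams chat_predict
#' @return List with `scores` (length m) and `recalled` (binary length m).
#' @export
chat_scores <- function(model, x) {
  stopifnot(inherits(model, "chat_model"))
  x <- as.numeric(x)
  assert_pattern_length(x, model$n)
  u <- drop(model$weights %*% translate(x, model$centroid))
  list(scores = u, recalled = as.integer(in_max_set(u)))
}

# Arg-max set membership under a sign-aware relative tolerance:
# u_i belongs iff max(u) - u_i <= tol * max(1, |max(u)|).
in_max_set <- function(u, tol = 1e-9) {
  mx <- max(u)
  (mx - u) <= tol * max(1, abs(mx))
}

which_max_tol <- function(u, tol = 1e-9) {
  which(in_max_set(u, tol))[1L]
}

#' @export
print.chat_model <- function(x, ...) {
  kind <- if (all(x$centroid == 0)) "CHA (no axis translation)" else "CHAT"
  cat(kind, " classifier: ", x$m, " classes, ", x$n, " features\n", sep = "")
  invisible(x)
}
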