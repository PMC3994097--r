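#' Train a Lernmatrix associative memory
#'
#' The Lernmatrix (Steinbuch) is a heteroassociative memory acting as a
#' binary pattern classifier. It stores associations between binary input
#' patterns \eqn{x \in \{0,1\}^n} and one-hot class codes \eqn{y \in
#' \{0,1\}^m}. Starting from the zero matrix, each association updates
#' component \eqn{m_{ij}} by \eqn{+\varepsilon} when \eqn{y_i = 1} and
#' \eqn{x_j = 1}, by \eqn{-\varepsilon} when \eqn{y_i = 1} and \eqn{x_j =
#' 0}, and leaves it unchanged when \eqn{y_i = 0}. The result is
#' order-independent: any permutation of the associations yields the same
#' memory.
#'
#' @param patterns binary patterns: a p x n matrix (rows are patterns) or a
#'   list of equal-length 0/1 vectors. Components must be exactly 0 or 1; no
#'   implicit thresholding of real values is performed.
#' @param labels integer class indices in `1..m`, one per pattern.
#' @param m number of classes (rows of the memory).
#' @param eps the learning constant \eqn{\varepsilon}; any positive real,
#'   default 1. Recall is invariant to its value.
#'
#' @return An object of class `lernmatrix`: list with `weights` (m x n
#'   matrix whose entries are integer multiples of eps), `eps`, `n`, `m`.
#' @seealso [lernmatrix_recall()]
#' @examples
#' M <- lernmatrix_learn(rbind(c(1, 0, 1), c(0, 1, 1)), c(1, 2), m = 2)
#' M$weights
#' lernmatrix_recall(M, c(1, 0, 1))
#' @export
lernmatrix_learn <- function(patterns, labels, m, eps = 1) {
  X <- as_binary_matrix(patterns)
  if (nrow(X) == 0L) stop("cannot learn from an empty pattern list")
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) stop("one label per pattern required")
  if (any(labels < 1L | labels > m)) {
    bad <- which(labels < 1L | labels > m)[1L]
    stop("label out of range [1, ", m, "] at pattern ", bad)
  }
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0) {
    stop("eps must be a single positive number")
  }
  n <- ncol(X)
  # One-hot class matrix Y (p x m); update is eps * t(Y) %*% (2X - 1):
  # +eps where the class row fires and x_j = 1, -eps where it fires and
  # x_j = 0, zero elsewhere.
  Y <- matrix(0, nrow(X), m)
  Y[cbind(seq_len(nrow(X)), labels)] <- 1
  W <- eps * crossprod(Y, 2 * X - 1)
  structure(list(weights = W, eps = eps, n = n, m = as.integer(m)),
            class = "lernmatrix")
}

#' Recall a class vector from a Lernmatrix
#'
#' Scores every class row against a binary query (`weights %*% x`) and flags
#' with 1 each row attaining the maximum score. Several components can be 1
#' when scores tie; at least one always is. Scores are integer multiples of
#' eps, so the maximum is compared exactly.
#'
#' @param memory a `lernmatrix` from [lernmatrix_learn()].
#' @param x binary query vector of length n.
#' @return Binary vector of length m: the arg-max set of class scores.
#' @export
lernmatrix_recall <- function(memory, x) {
  stopifnot(inherits(memory, "lernmatrix"))
  x <- as_binary_matrix(rbind(x))
  assert_pattern_length(drop(x), memory$n)
  scores <- drop(memory$weights %*% drop(x))
  as.integer(scores == max(scores))
}

#' Train a Linear Associator
#'
#' Learning proceeds in two steps: for each association \eqn{(x^\mu,
#' y^\mu)} form the outer product \eqn{y^\mu (x^\mu)^T}, then sum the p
#' resulting matrices into the memory \eqn{M = \sum_\mu y^\mu (x^\mu)^T}.
#' When the inputs are mutually orthonormal, recall of each fundamental
#' input reproduces its fundamental output exactly.
#'
#' @param inputs real input patterns: p x n matrix or list of vectors.
#' @param outputs real output patterns: p x q matrix or list of vectors.
#' @return Object of class `linear_associator`: list with `weights` (q x n),
#'   `n`, `q`.
#' @seealso [linear_associator_recall()]
#' @examples
#' M <- linear_associator_learn(diag(2), diag(2))
#' linear_associator_recall(M, c(0.3, -2))
#' @export
linear_associator_learn <- function(inputs, outputs) {
  X <- as_row_matrix(inputs, "inputs")
  Y <- as_row_matrix(outputs, "outputs")
  if (nrow(X) != nrow(Y)) stop("inputs and outputs must pair up one-to-one")
  if (nrow(X) < 1L) stop("at least one association is required")
  W <- crossprod(Y, X)  # sum_mu y^mu (x^mu)^T
  structure(list(weights = W, n = ncol(X), q = ncol(Y)),
            class = "linear_associator")
}

#' Recall from a Linear Associator
#'
#' Returns the raw matrix-vector product `weights %*% x`, with no
#' thresholding or normalization.
#'
#' @param memory a `linear_associator`.
#' @param x real query vector of length n.
#' @return Real vector of length q.
#' @export
linear_associator_recall <- function(memory, x) {
  stopifnot(inherits(memory, "linear_associator"))
  x <- as.numeric(x)
  assert_pattern_length(x, memory$n)
  drop(memory$weights %*% x)
}

as_row_matrix <- function(x, what = "patterns") {
  if (is.list(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) > 1L) {
      stop(what, " have inconsistent dimensions: lengths ",
           paste(unique(lens), collapse = ", "))
    }
    x <- do.call(rbind, lapply(x, as.numeric))
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

as_binary_matrix <- function(x) {
  X <- as_row_matrix(x, "binary patterns")
  bad <- which(!(X == 0 | X == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-binary component at pattern ", bad[1L, 1L], ", position ",
         bad[1L, 2L], " (value ", X[bad[1L, , drop = FALSE]], ")")
  }
  X
}
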