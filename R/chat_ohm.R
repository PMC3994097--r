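#' One-hot code for a training pattern
#'
#' Output coding used by CHAT-OHM: instead of one code per class, every
#' training pattern mu gets its own length-p output vector with a single 1
#' at position mu (Kronecker delta).
#'
#' @param mu pattern index in `1..p`.
#' @param p number of training patterns.
#' @return Binary vector of length p with a 1 at position `mu`.
#' @export
encode_one_hot <- function(mu, p) {
  mu <- as.integer(mu)
  if (mu < 1L || mu > p) stop("pattern index ", mu, " out of range [1, ", p, "]")
  v <- integer(p)
  v[mu] <- 1L
  v
}

#' Masking vectors for majority voting
#'
#' For each class k, the masking vector c^k is the length-p binary indicator
#' of which training patterns carry label k. The m masking vectors partition
#' the patterns: they sum component-wise to the all-ones vector.
#'
#' @param labels integer class indices in `1..m`, length p.
#' @param m number of classes.
#' @return m x p binary matrix; row k is the masking vector of class k.
#' @export
build_masking_vectors <- function(labels, m) {
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > m)) {
    stop("label out of range [1, ", m, "] at position ",
         which(labels < 1L | labels > m)[1L])
  }
  masks <- matrix(0L, m, length(labels))
  masks[cbind(labels, seq_along(labels))] <- 1L
  masks
}

#' Fit a CHAT-OHM classifier
#'
#' CHAT with per-pattern one-hot output coding. The training inputs are
#' translated to their centroid and learned as a Linear Associator whose
#' outputs are the length-p one-hot codes of [encode_one_hot()]; the
#' outer-product sum then reduces exactly to stacking the translated
#' patterns as rows, so `weights` is the p x n matrix of translated inputs.
#' Masking vectors record each pattern's class for the majority-voting
#' recall of [chat_ohm_predict()].
#'
#' @param data a [fundamental_set()].
#' @return Object of class `chat_ohm_model`: list with `centroid`,
#'   `weights` (p x n translated training matrix), `masks` (m x p binary),
#'   `label_map`, `n`, `m`, `p`.
#' @examples
#' fs <- fundamental_set(rbind(c(1, 1), c(3, 1), c(-1, -1), c(-3, -1)),
#'                       c(0, 0, 1, 1))
#' fit <- chat_ohm_fit(fs)
#' chat_ohm_predict(fit, c(2, 1))
#' @export
chat_ohm_fit <- function(data) {
  stopifnot(inherits(data, "fundamental_set"))
  if (anyNA(data$X)) stop("training data contain missing values; impute or drop them first")
  centroid <- compute_centroid(data$X)
  Xhat <- translate(data$X, centroid)
  structure(
    list(centroid = centroid, weights = Xhat,
         masks = build_masking_vectors(data$labels, data$m),
         label_map = data$label_map, n = ncol(Xhat), m = data$m,
         p = nrow(Xhat)),
    class = "chat_ohm_model"
  )
}

#' Lernmatrix-style recovery of a CHAT-OHM model
#'
#' Translates the query, scores every training pattern by its inner product
#' with the translated query (`u = weights %*% x_hat`), and flags the
#' arg-max set: component i is 1 iff `max(u) - u_i <= 1e-9 * max(1,
#' |max(u)|)`. Because outputs were coded per pattern, this recovered vector
#' has length p and still needs the extract/majority-voting step to become a
#' class.
#'
#' @param model a `chat_ohm_model`.
#' @param x numeric query vector of length n.
#' @return Binary vector of length p (at least one component is 1).
#' @seealso [count_votes()], [chat_ohm_predict()]
#' @export
chat_ohm_recover <- function(model, x) {
  stopifnot(inherits(model, "chat_ohm_model"))
  x <- as.numeric(x)
  assert_pattern_length(x, model$n)
  u <- drop(model$weights %*% translate(x, model$centroid))
  as.integer(in_max_set(u))
}

#' Count class votes from a recovered vector
#'
#' For each class k the counting vector t^k is the component-wise AND of
#' the recovered vector and masking vector c^k; its sum is class k's vote.
#' Votes over all classes sum to the number of 1s in the recovered vector.
#'
#' @param recovered binary vector of length p ([chat_ohm_recover()]).
#' @param masks m x p binary matrix ([build_masking_vectors()]).
#' @return Integer vector of m vote counts.
#' @export
count_votes <- function(recovered, masks) {
  recovered <- as.integer(recovered)
  if (length(recovered) != ncol(masks)) {
    stop("recovered vector length ", length(recovered),
         " does not match mask length ", ncol(masks))
  }
  as.integer(masks %*% recovered)
}

#' Classify with a CHAT-OHM model
#'
#' Full recall: recover the arg-max set of training patterns, AND it with
#' each class's masking vector, and return the label with the largest vote
#' count (majority voting). Vote ties go to the smallest class index.
#'
#' @param model a `chat_ohm_model` from [chat_ohm_fit()].
#' @param x query vector of length n, or a matrix of queries (one per row).
#' @return Predicted label(s) in the original label coding.
#' @export
chat_ohm_predict <- function(model, x) {
  stopifnot(inherits(model, "chat_ohm_model"))
  Xq <- if (is.matrix(x)) x else rbind(as.numeric(x))
  if (ncol(Xq) != model$n) stop("query has ", ncol(Xq), " features, expected ", model$n)
  U <- model$weights %*% t(translate(Xq, model$centroid))  # p x nq
  mx <- apply(U, 2L, max)
  R <- sweep(U, 2L, mx, function(u, m) (m - u) <= 1e-9 * pmax(1, abs(m)))
  votes <- model$masks %*% R  # m x nq
  idx <- apply(votes, 2L, which.max)  # first maximum = smallest class index
  out <- decode_labels(model$label_map, idx)
  if (is.matrix(x)) out else out[[1L]]
}

#' @export
print.chat_ohm_model <- function(x, ...) {
  cat("CHAT-OHM classifier: ", x$p, " stored patterns, ", x$m, " classes, ",
      x$n, " features\n", sep = "")
  invisible(x)
}
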