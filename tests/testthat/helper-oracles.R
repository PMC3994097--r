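# Independent brute-force oracles, kept deliberately naive (explicit loops)
# so they share no code path with the implementation they check.

# Steinbuch update rule replayed component by component.
oracle_lernmatrix <- function(X, labels, m, eps = 1) {
  W <- matrix(0, m, ncol(X))
  for (mu in seq_len(nrow(X))) {
    for (i in seq_len(m)) {
      if (i != labels[mu]) next
      for (j in seq_len(ncol(X))) {
        W[i, j] <- W[i, j] + if (X[mu, j] == 1) eps else -eps
      }
    }
  }
  W
}

# Arg-max set of row scores by explicit dot products.
oracle_lernmatrix_recall <- function(W, x) {
  scores <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) {
    s <- 0
    for (j in seq_along(x)) s <- s + W[i, j] * x[j]
    scores[i] <- s
  }
  as.integer(scores == max(scores))
}

# Outer-product accumulation by triple loop.
oracle_linear_associator <- function(X, Y) {
  W <- matrix(0, ncol(Y), ncol(X))
  for (mu in seq_len(nrow(X))) {
    for (i in seq_len(ncol(Y))) {
      for (j in seq_len(ncol(X))) {
        W[i, j] <- W[i, j] + Y[mu, i] * X[mu, j]
      }
    }
  }
  W
}

# Label of the training pattern with the largest centered inner product
# with the query; NA when the maximum is not unique (caller skips those).
oracle_nn_label <- function(X, labels, query) {
  centroid <- colMeans(X)
  scores <- numeric(nrow(X))
  for (mu in seq_len(nrow(X))) {
    scores[mu] <- sum((X[mu, ] - centroid) * (query - centroid))
  }
  top <- which(scores == max(scores))
  if (length(top) > 1L) return(NA_integer_)
  labels[top]
}

# Classic simultaneous-pass ENN with the package's documented tie rules:
# k-th-neighbour distance ties -> lower row index; neighbour-label
# plurality ties -> keep the row.
oracle_enn_removed <- function(X, labels, m, k = 3) {
  p <- nrow(X)
  removed <- integer(0)
  for (i in seq_len(p)) {
    d <- rep(Inf, p)
    for (h in seq_len(p)) {
      if (h != i) d[h] <- sqrt(sum((X[i, ] - X[h, ])^2))
    }
    nb <- order(d, seq_len(p))[seq_len(k)]
    counts <- integer(m)
    for (h in nb) counts[labels[h]] <- counts[labels[h]] + 1L
    winners <- which(counts == max(counts))
    if (length(winners) == 1L && winners != labels[i]) removed <- c(removed, i)
  }
  removed
}

# Random binary pattern matrix without duplicate all-equal degeneracy.
random_binary <- function(p, n) {
  matrix(sample(0:1, p * n, replace = TRUE), p, n)
}

# Two-class Gaussian blob fundamental set used across property tests.
random_blob_set <- function(seed, sep = 6, sigma = 1, counts = c(15, 15), n = 3) {
  means <- rbind(c(rep(0, n - 1), -sep / 2), c(rep(0, n - 1), sep / 2))
  make_blobs(blob_spec(means = means, sigma = sigma, counts = counts, seed = seed))
}
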