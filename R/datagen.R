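#' Specification of Gaussian blob data
#'
#' Class-dependent isotropic Gaussians: class k draws `counts[k]` patterns
#' from N(means[k,], sigma^2 I). Separable (means far apart relative to
#' sigma) and overlapping (means close) regimes cover the two situations a
#' nearest-pattern classifier faces on clinical tabular data.
#'
#' @param means m x n matrix of per-class mean vectors.
#' @param sigma shared isotropic standard deviation, >= 0.
#' @param counts integer vector of per-class pattern counts, each >= 1.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return Object of class `blob_spec`.
#' @export
blob_spec <- function(means, sigma = 1, counts, seed = 1) {
  means <- as.matrix(means)
  if (sigma < 0) stop("sigma must be >= 0")
  if (length(counts) != nrow(means)) stop("one count per class mean required")
  if (any(counts < 1)) stop("every class needs at least one pattern")
  structure(list(means = means, sigma = sigma, counts = as.integer(counts),
                 seed = as.integer(seed)),
            class = "blob_spec")
}

#' Generate Gaussian blob data
#'
#' @param spec a [blob_spec()].
#' @return A [fundamental_set()] with integer class labels `1..m`;
#'   deterministic given the spec's seed.
#' @examples
#' fs <- make_blobs(blob_spec(means = rbind(c(-10, 0), c(10, 0)),
#'                            sigma = 1, counts = c(50, 50), seed = 42))
#' @export
make_blobs <- function(spec) {
  stopifnot(inherits(spec, "blob_spec"))
  set.seed(spec$seed)
  m <- nrow(spec$means)
  n <- ncol(spec$means)
  X <- do.call(rbind, lapply(seq_len(m), function(k) {
    sweep(matrix(stats::rnorm(spec$counts[k] * n, sd = spec$sigma),
                 spec$counts[k], n),
          2L, spec$means[k, ], "+")
  }))
  fundamental_set(X, rep(seq_len(m), spec$counts))
}

#' Symmetric tie fixture
#'
#' Constructs a training set and a query whose centered inner-product
#' scores tie exactly, exercising the recovery and majority-voting tie
#' paths that unique maxima never reach. With `classes = 2` the set is
#' `{(1,0) -> class 1, (0,1) -> class 2}` and the query `(0.5, 0.5)` (the
#' centroid): every score is zero, the recovered vector is all ones, and
#' the vote ties. With `classes = 3` the patterns are three rotationally
#' symmetric unit vectors and the query is the centroid, giving a
#' three-way tie.
#'
#' @param classes 2 (default) or 3.
#' @return List with `data` (a [fundamental_set()]) and `query` (numeric
#'   vector).
#' @export
make_tie_fixture <- function(classes = 2) {
  if (classes == 2) {
    X <- rbind(c(1, 0), c(0, 1))
  } else if (classes == 3) {
    ang <- 2 * pi * (0:2) / 3
    X <- cbind(cos(ang), sin(ang))
  } else {
    stop("tie fixture supports 2 or 3 classes")
  }
  list(data = fundamental_set(X, seq_len(classes)),
       query = compute_centroid(X))
}

#' Corruption specification
#'
#' @param n_missing number of rows to receive a missing marker (one `NA`
#'   cell each, at a random column).
#' @param n_outliers number of label-flipped boundary patterns: existing
#'   rows are re-drawn near a foreign class mean while keeping their
#'   original label, creating exactly the atypical patterns Wilson editing
#'   targets.
#' @param seed RNG seed.
#' @return Object of class `corruption_spec`.
#' @export
corruption_spec <- function(n_missing = 0, n_outliers = 0, seed = 1) {
  if (n_missing < 0 || n_outliers < 0) stop("corruption counts must be >= 0")
  structure(list(n_missing = as.integer(n_missing),
                 n_outliers = as.integer(n_outliers),
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Corrupt a dataset with missing markers and planted outliers
#'
#' Plants exactly the requested number of missing-bearing rows and
#' label-flipped outlier rows, returning their ground-truth indices so
#' downstream tests never re-derive them. Outliers are planted by moving a
#' row to a draw from a different class's blob (the class centroid of the
#' other rows, plus noise at the set's residual scale) while keeping its
#' label, so its neighbours all disagree with it.
#'
#' @param data a [fundamental_set()].
#' @param spec a [corruption_spec()]. Missing and outlier rows are chosen
#'   disjointly; the total must not exceed the number of rows.
#' @return List with `data` (corrupted [fundamental_set()]),
#'   `outlier_indices`, `missing_indices`.
#' @export
corrupt <- function(data, spec) {
  stopifnot(inherits(data, "fundamental_set"), inherits(spec, "corruption_spec"))
  p <- nrow(data$X)
  if (spec$n_missing + spec$n_outliers > p) {
    stop("requested corruption (", spec$n_missing + spec$n_outliers,
         " rows) exceeds available rows (", p, ")")
  }
  set.seed(spec$seed)
  X <- data$X
  chosen <- sample(p, spec$n_missing + spec$n_outliers)
  out_idx <- sort(chosen[seq_len(spec$n_outliers)])
  miss_idx <- sort(chosen[spec$n_outliers + seq_len(spec$n_missing)])
  if (spec$n_outliers > 0L && data$m < 2L) {
    stop("planting outliers requires at least two classes")
  }
  # Each outlier sits beside a DISTINCT uncorrupted foreign-class row (tiny
  # jitter), so its whole neighbourhood carries the foreign label; planted
  # outliers cannot shelter one another from the nearest-neighbour vote.
  used_anchors <- integer(0)
  for (i in out_idx) {
    own <- data$labels[i]
    anchors <- setdiff(which(data$labels != own), c(chosen, used_anchors))
    if (length(anchors) == 0L) stop("not enough clean foreign rows to plant outliers")
    anchor <- if (length(anchors) == 1L) anchors else sample(anchors, 1L)
    used_anchors <- c(used_anchors, anchor)
    scale <- mean(apply(data$X, 2L, stats::sd))
    X[i, ] <- data$X[anchor, ] + stats::rnorm(ncol(X), sd = 1e-3 * scale)
  }
  for (i in miss_idx) {
    X[i, sample(ncol(X), 1L)] <- NA_real_
  }
  list(data = fundamental_set(X, decode_labels(data, data$labels),
                              label_map = data$label_map),
       outlier_indices = out_idx, missing_indices = miss_idx)
}
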