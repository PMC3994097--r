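#' Classification success rate
#'
#' The proportion of test instances whose predicted class equals the actual
#' class, expressed as a percentage.
#'
#' @param predicted,actual label vectors of equal nonzero length; compared
#'   after coercion to character, so factor/integer/string codings mix
#'   safely.
#' @return A percentage in `[0, 100]`.
#' @export
accuracy <- function(predicted, actual) {
  if (length(predicted) == 0L) stop("cannot score an empty prediction list")
  if (length(predicted) != length(actual)) {
    stop("predicted (", length(predicted), ") and actual (", length(actual),
         ") lengths differ")
  }
  100 * mean(as.character(predicted) == as.character(actual))
}

#' Cross-validation configuration
#'
#' @param folds number of folds, default 10.
#' @param repeats number of repetitions with fresh random re-ordering,
#'   default 10.
#' @param seed master seed; per-repeat shuffles use a derived substream (see
#'   the methods vignette) so any repeat is reproducible in isolation.
#' @param shuffle randomly re-order patterns within each class before fold
#'   dealing (default `TRUE`); with `FALSE` folds are dealt in row order.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(folds = 10, repeats = 10, seed = 1, shuffle = TRUE) {
  if (folds < 2) stop("at least 2 folds required")
  if (repeats < 1) stop("at least 1 repeat required")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), shuffle = isTRUE(shuffle)),
            class = "cv_config")
}

# Derived seed for repeat r; stays below 2^31 - 1.
substream_seed <- function(seed, r) {
  as.integer((as.double(seed) %% 44488 * 48271 + 31 * r) %% 2147483647)
}

#' Stratified fold assignment
#'
#' Divides the rows into folds in which each class is represented in
#' approximately the same proportion as in the full set: within each class
#' the (optionally shuffled) instances are dealt round-robin to folds
#' 1..folds, so per-class per-fold counts differ by at most one and
#' remainder instances land in the lowest-indexed folds.
#'
#' @param labels integer class indices (any values; grouped by equality).
#' @param config a [cv_config()]. The caller owns the RNG state: seed it
#'   before calling for reproducible shuffles (as [cross_validate()] does).
#' @return Integer vector: fold index in `1..folds` per row.
#' @export
stratified_folds <- function(labels, config) {
  stopifnot(inherits(config, "cv_config"))
  p <- length(labels)
  if (p < config$folds) stop("fewer instances (", p, ") than folds (", config$folds, ")")
  sizes <- table(labels)
  if (min(sizes) < config$folds) {
    warning("smallest class (", min(sizes), ") has fewer instances than folds (",
            config$folds, "); stratification degraded")
  }
  fold <- integer(p)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (config$shuffle) idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(config$folds), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' The validation protocol used throughout the package: for each repeat the
#' patterns are randomly re-ordered (a repeat-specific substream of the
#' master seed), stratified folds are built, and each fold in turn is held
#' out while the classifier trains on the remaining folds; the success rate
#' is recorded per fold and all repeats x folds rates are averaged into the
#' overall mean.
#'
#' Preprocessing stages run either on the full dataset before
#' cross-validation (`per_fold = FALSE`, the default, matching pipelines
#' that condition a dataset once and then validate) or inside each fold
#' (`per_fold = TRUE`, leakage-free): z-score statistics are then fit on
#' the training folds only and applied to the held-out fold, and Wilson
#' editing removes training rows only. Imputation and row deletion always
#' run on the full dataset before validation (test instances carry no label
#' at predict time, and rates are only comparable on a fixed instance set).
#'
#' @param data a [fundamental_set()].
#' @param classifier `"chat-ohm"`, `"chat"`, `"cha"`, or a list with
#'   functions `fit(fundamental_set)` and `predict(model, X)` for a custom
#'   classifier.
#' @param config a [cv_config()].
#' @param stages character vector of preprocessing stages applied in order,
#'   drawn from `"drop_missing"`, `"impute"`, `"normalize"`,
#'   `"wilson_edit"`; default none. Stage order expresses the experimental
#'   conditions "original", "normalized", "without outliers", "normalized
#'   without outliers".
#' @param schema an [attribute_schema()], required when `stages` contains
#'   `"impute"`.
#' @param per_fold run `"normalize"`/`"wilson_edit"` inside each training
#'   fold instead of once on the full dataset.
#' @param wilson_k neighbour count for Wilson editing, default 3.
#' @return Object of class `cv_result`: list with `rates` (repeats x folds
#'   matrix of percentages), `per_repeat_means`, `mean` (grand mean over all
#'   entries), and the `config`.
#' @examples
#' fs <- make_blobs(blob_spec(means = rbind(c(-10, 0), c(10, 0)),
#'                            sigma = 1, counts = c(20, 20), seed = 7))
#' cv <- cross_validate(fs, "chat-ohm", cv_config(folds = 5, repeats = 2, seed = 1))
#' cv$mean
#' @export
cross_validate <- function(data, classifier = "chat-ohm", config = cv_config(),
                           stages = character(), schema = NULL,
                           per_fold = FALSE, wilson_k = 3) {
  stopifnot(inherits(data, "fundamental_set"), inherits(config, "cv_config"))
  clf <- resolve_classifier(classifier)
  global_stages <- if (per_fold) setdiff(stages, c("normalize", "wilson_edit")) else stages
  fold_stages <- if (per_fold) intersect(stages, c("normalize", "wilson_edit")) else character()
  data <- apply_stages(data, global_stages, schema, wilson_k)

  rates <- matrix(NA_real_, config$repeats, config$folds,
                  dimnames = list(repeat_ = seq_len(config$repeats),
                                  fold = seq_len(config$folds)))
  for (r in seq_len(config$repeats)) {
    set.seed(substream_seed(config$seed, r))
    fold <- stratified_folds(data$labels, config)
    for (f in seq_len(config$folds)) {
      train <- data[fold != f]
      test_X <- data$X[fold == f, , drop = FALSE]
      test_lab <- decode_labels(data, data$labels[fold == f])
      for (st in fold_stages) {
        if (st == "wilson_edit") {
          train <- train[wilson_edit(train, k = wilson_k)$kept_indices]
        } else if (st == "normalize") {
          zs <- zscore_fit(train$X)
          train$X <- zscore_apply(train$X, zs)
          test_X <- zscore_apply(test_X, zs)
        }
      }
      model <- tryCatch(clf$fit(train), error = function(e) {
        stop("classifier failed on repeat ", r, ", fold ", f, ": ",
             conditionMessage(e))
      })
      rates[r, f] <- accuracy(clf$predict(model, test_X), test_lab)
    }
  }
  structure(list(rates = rates, per_repeat_means = rowMeans(rates),
                 mean = mean(rates), config = config),
            class = "cv_result")
}

apply_stages <- function(data, stages, schema, wilson_k) {
  for (st in stages) {
    data <- switch(
      st,
      drop_missing = {
        d <- drop_missing_rows(data$X, data$labels)
        fundamental_set(d$X, decode_labels(data, d$labels),
                        label_map = data$label_map)
      },
      impute = {
        if (is.null(schema)) stop("stage 'impute' requires an attribute_schema")
        fundamental_set(impute_class_conditional(data$X, data$labels, schema),
                        decode_labels(data, data$labels),
                        label_map = data$label_map)
      },
      normalize = {
        data$X <- zscore_apply(data$X, zscore_fit(data$X))
        data
      },
      wilson_edit = data[wilson_edit(data, k = wilson_k)$kept_indices],
      stop("unknown preprocessing stage: ", st)
    )
  }
  data
}

resolve_classifier <- function(classifier) {
  if (is.list(classifier)) {
    stopifnot(is.function(classifier$fit), is.function(classifier$predict))
    return(classifier)
  }
  switch(
    match.arg(classifier, c("chat-ohm", "chat", "cha")),
    "chat-ohm" = list(fit = chat_ohm_fit, predict = chat_ohm_predict),
    "chat" = list(fit = chat_fit, predict = chat_predict),
    "cha" = list(fit = function(d) chat_fit(d, translate_axes = FALSE),
                 predict = chat_predict)
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Repeated stratified cross-validation: ", x$config$repeats, " x ",
      x$config$folds, "-fold\n", sep = "")
  cat(sprintf("Overall mean accuracy: %.2f%%\n", x$mean))
  cat(sprintf("Per-repeat means: %s\n",
              paste(sprintf("%.2f", x$per_repeat_means), collapse = " ")))
  invisible(x)
}

#' Export a cross-validation result
#'
#' `cv_to_csv()` writes the long table (repeat, fold, accuracy);
#' `cv_to_json()` writes a summary with the grand mean, per-repeat means
#' and the full rate matrix.
#'
#' @param result a `cv_result` from [cross_validate()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
cv_to_csv <- function(result, path) {
  stopifnot(inherits(result, "cv_result"))
  long <- data.frame(
    repeat_ = rep(seq_len(nrow(result$rates)), each = ncol(result$rates)),
    fold = rep(seq_len(ncol(result$rates)), nrow(result$rates)),
    accuracy = as.vector(t(result$rates))
  )
  names(long)[1] <- "repeat"
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cv_to_csv
#' @export
cv_to_json <- function(result, path) {
  stopifnot(inherits(result, "cv_result"))
  jsonlite::write_json(
    list(mean = result$mean, per_repeat_means = result$per_repeat_means,
         rates = result$rates,
         folds = result$config$folds, repeats = result$config$repeats,
         seed = result$config$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
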