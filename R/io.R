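#' Dataset configuration
#'
#' Describes how to read a labeled tabular file: format, class column,
#' per-column attribute kinds, missing marker and header flag. UCI-style
#' files vary (class first or last, "?" for missing); the config expresses
#' those differences without per-dataset code. Configs can be written by
#' hand or loaded from a JSON/YAML file with [read_dataset_config()].
#'
#' @param path data file path.
#' @param format `"csv"` (default) or `"arff"`.
#' @param class_col class column: 1-based index or column name. Default:
#'   the last column.
#' @param kinds per-feature-column attribute kinds
#'   ("continuous"/"categorical"); default `NULL` guesses: columns that
#'   parse fully as numbers are continuous, the rest categorical.
#' @param missing_marker string marking missing cells, default `"?"`.
#' @param header does the file start with a header row? Default `FALSE`
#'   (the UCI convention).
#' @return Object of class `dataset_config`.
#' @export
dataset_config <- function(path, format = c("csv", "arff"), class_col = NULL,
                           kinds = NULL, missing_marker = "?",
                           header = FALSE) {
  structure(list(path = path, format = match.arg(format),
                 class_col = class_col, kinds = kinds,
                 missing_marker = missing_marker, header = isTRUE(header)),
            class = "dataset_config")
}

#' Load a dataset configuration from JSON or YAML
#'
#' Recognised fields: `path`, `format`, `class_col`, `kinds`,
#' `missing_marker`, `header`, plus the pipeline fields `stages`,
#' `per_fold` consumed by the CLI. Relative data paths are resolved against
#' the config file's directory.
#'
#' @param file path to a `.json`, `.yaml` or `.yml` file.
#' @return List with `config` (a [dataset_config()]), `stages`, `per_fold`.
#' @export
read_dataset_config <- function(file) {
  raw <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
  if (is.null(raw$path)) stop("config is missing the 'path' field")
  if (!file.exists(raw$path)) {
    cand <- file.path(dirname(file), raw$path)
    if (file.exists(cand)) raw$path <- cand
  }
  cfg <- dataset_config(
    path = raw$path,
    format = if (is.null(raw$format)) "csv" else raw$format,
    class_col = raw$class_col,
    kinds = raw$kinds,
    missing_marker = if (is.null(raw$missing_marker)) "?" else raw$missing_marker,
    header = isTRUE(raw$header)
  )
  list(config = cfg, stages = as.character(raw$stages %||% character()),
       per_fold = isTRUE(raw$per_fold))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a labeled tabular dataset
#'
#' Parses a CSV or ARFF file into a [fundamental_set()] plus its
#' [attribute_schema()] and missing mask. Numeric columns are parsed as
#' reals; categorical columns are integer-coded with the dictionary stored
#' in the schema; cells equal to the missing marker become `NA` in the
#' matrix and are flagged in the mask — never silently zeroed or imputed.
#' Class labels are mapped to internal indices with the original labels
#' preserved in the label map.
#'
#' @param config a [dataset_config()].
#' @return List with `data` (a [fundamental_set()], `NA` where missing),
#'   `schema` (an [attribute_schema()] with a `dictionaries` attribute for
#'   categorical columns), and `missing_mask` (logical p x n matrix).
#' @export
read_dataset <- function(config) {
  stopifnot(inherits(config, "dataset_config"))
  if (!file.exists(config$path)) stop("data file not found: ", config$path)
  df <- switch(
    config$format,
    csv = utils::read.csv(config$path, header = config$header,
                          na.strings = config$missing_marker,
                          colClasses = "character",
                          strip.white = TRUE, check.names = FALSE),
    arff = foreign::read.arff(config$path)
  )
  if (nrow(df) == 0L) stop("empty dataset: ", config$path)

  cc <- config$class_col %||% ncol(df)
  if (is.character(cc)) {
    cc_idx <- match(cc, colnames(df))
    if (is.na(cc_idx)) stop("unknown class column: ", cc)
  } else {
    cc_idx <- as.integer(cc)
    if (cc_idx < 1L || cc_idx > ncol(df)) stop("class column index out of range: ", cc_idx)
  }
  labels <- as.character(df[[cc_idx]])
  if (anyNA(labels)) stop("missing class label at row ", which(is.na(labels))[1L])
  feat <- df[, -cc_idx, drop = FALSE]
  n <- ncol(feat)

  kinds <- config$kinds
  if (is.null(kinds)) {
    kinds <- vapply(feat, function(col) {
      v <- as.character(col)
      obs <- v[!is.na(v)]
      num <- suppressWarnings(as.numeric(obs))
      if (length(obs) > 0L && !anyNA(num)) "continuous" else "categorical"
    }, character(1))
  }
  if (length(kinds) != n) {
    stop("config declares ", length(kinds), " attribute kinds for ", n,
         " feature columns")
  }

  X <- matrix(NA_real_, nrow(feat), n)
  dicts <- vector("list", n)
  for (j in seq_len(n)) {
    v <- as.character(feat[[j]])
    obs <- !is.na(v)
    if (kinds[j] == "continuous") {
      num <- suppressWarnings(as.numeric(v[obs]))
      if (anyNA(num)) {
        bad <- which(obs)[which(is.na(num))[1L]]
        stop("unparseable numeric cell at row ", bad, ", feature column ", j,
             ": '", v[bad], "'")
      }
      X[obs, j] <- num
    } else {
      dicts[[j]] <- sort(unique(v[obs]))
      X[obs, j] <- match(v[obs], dicts[[j]])
    }
  }
  schema <- attribute_schema(kinds, class_col = cc,
                             missing_marker = config$missing_marker)
  attr(schema, "dictionaries") <- dicts
  list(data = fundamental_set(X, labels),
       schema = schema,
       missing_mask = is.na(X))
}

MODEL_FORMAT_VERSION <- 1L

#' Save a fitted model to a text file
#'
#' Serializes Lernmatrix, CHAT and CHAT-OHM models (optionally with fitted
#' preprocessing statistics) to a versioned JSON file. Numbers are written
#' with 17 significant digits, which round-trips IEEE doubles exactly, so
#' a reloaded model reproduces predictions bit-identically.
#'
#' @param model a `lernmatrix`, `chat_model` or `chat_ohm_model`.
#' @param path output file path.
#' @param preprocessing optional `zscore_stats` to store alongside (applied
#'   at predict time by the CLI).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, preprocessing = NULL) {
  family <- c(lernmatrix = "lernmatrix", chat_model = "chat",
              chat_ohm_model = "chat-ohm")[class(model)[1L]]
  if (is.na(family)) stop("unsupported model class: ", class(model)[1L])
  payload <- list(format_version = MODEL_FORMAT_VERSION, family = unname(family),
                  model = unclass(model))
  if (!is.null(preprocessing)) payload$preprocessing <- unclass(preprocessing)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path file written by [save_model()].
#' @return List with `model` (class restored), `family` tag, and
#'   `preprocessing` (a `zscore_stats` or `NULL`).
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  raw <- tryCatch(suppressWarnings(jsonlite::read_json(path, simplifyVector = TRUE)),
                  error = function(e) {
                    stop("cannot parse model file ", path, ": ",
                         conditionMessage(e))
                  })
  if (is.null(raw$format_version) || is.null(raw$family) || is.null(raw$model)) {
    stop("not a model file (missing format_version/family/model): ", path)
  }
  if (raw$format_version != MODEL_FORMAT_VERSION) {
    stop("model format version ", raw$format_version,
         " not supported (expected ", MODEL_FORMAT_VERSION, ")")
  }
  mod <- raw$model
  cls <- c(lernmatrix = "lernmatrix", chat = "chat_model",
           "chat-ohm" = "chat_ohm_model")[raw$family]
  if (is.na(cls)) stop("unknown model family: ", raw$family)
  mod <- restore_model_numerics(mod, cls)
  class(mod) <- cls
  prep <- NULL
  if (!is.null(raw$preprocessing)) {
    prep <- raw$preprocessing
    class(prep) <- "zscore_stats"
  }
  list(model = mod, family = unname(raw$family), preprocessing = prep)
}

restore_model_numerics <- function(mod, cls) {
  as_mat <- function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    dimnames(x) <- NULL
    x
  }
  mod$weights <- as_mat(mod$weights)
  if (!is.null(mod$masks)) {
    mod$masks <- as_mat(mod$masks)
    storage.mode(mod$masks) <- "integer"
  }
  for (f in c("n", "m", "p")) if (!is.null(mod[[f]])) mod[[f]] <- as.integer(mod[[f]])
  if (!is.null(mod$centroid)) mod$centroid <- as.numeric(mod$centroid)
  if (!is.null(mod$label_map)) mod$label_map <- as.character(mod$label_map)
  mod
}
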