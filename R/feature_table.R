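#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data :=
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
#' @importFrom stats predict sd var rnorm runif setNames kmeans quantile
#' @importFrom utils head
NULL

#' Default feature column names
#'
#' The three descriptors of the coarse-grained rubber system: `omega`, the
#' total phospholipid + protein mass fraction (unitless); `eps_h`, the
#' hydrogen-bond interaction strength (kcal/mol); and `eps_nh`, the
#' non-hydrogen-bond interaction strength (kcal/mol).
#'
#' @return Character vector of length 3.
#' @export
default_features <- function() c("omega", "eps_h", "eps_nh")

stop_stressaug <- function(msg, class) {
  abort(msg, class = c(paste0("stressaug_error_", class), "stressaug_error"))
}

#' Validate a feature table
#'
#' Checks that `data` carries the named numeric feature columns (and target,
#' when required) with no missing values, and that any `provenance` column
#' only holds the recognised tags.
#'
#' @param data A data frame of samples.
#' @param features Character vector of feature column names.
#' @param target Name of the target column, or `NULL`.
#' @param require_target Must the target column be present?
#' @return `data` as a tibble, invisibly usable in a pipe.
#' @export
validate_feature_table <- function(data, features = default_features(),
                                   target = NULL, require_target = FALSE) {
  if (!is.data.frame(data)) {
    stop_stressaug("`data` must be a data frame.", "type")
  }
  data <- tibble::as_tibble(data)
  if (length(features) < 1) {
    stop_stressaug("At least one feature column is required.", "no_features")
  }
  if (nrow(data) < 1) {
    stop_stressaug("Feature table has no rows.", "empty")
  }
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0) {
    stop_stressaug(
      paste0("Missing feature column(s): ", paste(missing_cols, collapse = ", ")),
      "missing_feature"
    )
  }
  if (!is.null(target) && require_target && !target %in% names(data)) {
    stop_stressaug(paste0("Missing target column '", target, "'."), "missing_target")
  }
  check_cols <- c(features, if (!is.null(target) && target %in% names(data)) target)
  for (col in check_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      stop_stressaug(paste0("Column '", col, "' is not numeric."), "nonnumeric")
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop_stressaug(paste0("Column '", col, "' contains missing or non-finite values."),
                     "missing_values")
    }
  }
  if ("provenance" %in% names(data)) {
    bad <- setdiff(unique(data$provenance), c("original", "nni", "smote"))
    if (length(bad) > 0) {
      stop_stressaug(paste0("Unknown provenance tag(s): ", paste(bad, collapse = ", ")),
                     "provenance")
    }
  }
  data
}

#' Read a feature table from CSV
#'
#' Reads a comma-separated file with a mandatory header row into a tibble and
#' validates it. Rows read from disk are tagged `original` in the
#' `provenance` column unless the file already carries one.
#'
#' @param path Path to a CSV file.
#' @param features Feature column names expected in the file.
#' @param target Target column name.
#' @param has_target Is the target column required to be present?
#' @return A tibble with the feature columns, target (if present) and a
#'   `provenance` column.
#' @export
read_feature_table <- function(path, features = default_features(),
                               target = "ts", has_target = TRUE) {
  if (!file.exists(path)) {
    stop_stressaug(paste0("File not found: ", path), "missing_file")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  data <- tibble::as_tibble(data)
  if (!"provenance" %in% names(data)) {
    data$provenance <- rep("original", nrow(data))
  }
  validate_feature_table(data, features = features, target = target,
                         require_target = has_target)
}

#' Write a feature table to CSV
#'
#' Writes comma-separated UTF-8 with a header row and "." as the decimal
#' mark. The `provenance` column is written only when any row is synthetic.
#'
#' @param data A validated feature table.
#' @param path Output file path.
#' @param features,target Column names to validate before writing.
#' @return `data`, invisibly.
#' @export
write_feature_table <- function(data, path, features = default_features(),
                                target = "ts") {
  data <- validate_feature_table(data, features = features, target = target)
  out <- data
  if ("provenance" %in% names(out) && all(out$provenance == "original")) {
    out$provenance <- NULL
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(data)
}

# Deterministic per-stage substream of a global seed, so any stage can be
# re-run in isolation and reproduce the pipeline's draw for that stage.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
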