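#' Coefficient of determination
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. May be negative for
#' predictors worse than the observed mean. Requires at least two
#' observations and a non-constant `y`.
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @return Scalar R-squared.
#' @export
r2_score <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_stressaug("`y` and `yhat` differ in length.", "length")
  if (length(y) < 2) stop_stressaug("Need at least 2 observations.", "too_few_rows")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop_stressaug("`y` is constant; R-squared is undefined.", "constant_y")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Coverage: fraction of predictions within twice the spread of |y|
#'
#' `Cov = mean( h( |y_i - yhat_i| / (2 * sd(|y_i|)) ) )` with h(x) = 1 for
#' x <= 1 and 0 otherwise, i.e. the fraction of predictions whose absolute
#' error is at most twice the standard deviation of the absolute observed
#' values. The boundary (error exactly equal to twice the spread) counts as
#' covered. The spread is computed over the evaluation set with the usual
#' N - 1 denominator.
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @return Scalar in [0, 1].
#' @export
coverage <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_stressaug("`y` and `yhat` differ in length.", "length")
  if (length(y) < 2) stop_stressaug("Need at least 2 observations.", "too_few_rows")
  spread <- sd(abs(y))
  if (spread == 0) {
    stop_stressaug("sd(|y|) is zero; coverage is undefined.", "constant_y")
  }
  mean(abs(y - yhat) / (2 * spread) <= 1)
}

#' Evaluation specification
#'
#' @param n_splits Number of random train/test splits (default 999).
#' @param test_fraction Fraction of rows held out per split, in (0, 1)
#'   (default 0.1, mirroring the 10-fold training regime).
#' @param test_originals_only Draw test rows only from rows with provenance
#'   `"original"`? Guards against optimism from synthetic rows that neighbour
#'   their training parents.
#' @return An `eval_spec` list.
#' @export
eval_spec <- function(n_splits = 999, test_fraction = 0.1,
                      test_originals_only = FALSE) {
  if (n_splits < 1) stop_stressaug("`n_splits` must be >= 1.", "spec")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_stressaug("`test_fraction` must be in (0, 1).", "spec")
  }
  structure(list(n_splits = as.integer(n_splits), test_fraction = test_fraction,
                 test_originals_only = test_originals_only),
            class = "eval_spec")
}

#' Repeated random-split robustness evaluation
#'
#' For each of `n_splits` seeded random train/test splits, fits every model
#' recipe on the training part and records out-of-sample R-squared and
#' coverage on the held-out part. Augmentation is not re-run per split: the
#' splits operate on the supplied table as-is. With
#' `test_originals_only = TRUE` the held-out rows are drawn from the original
#' rows only (a `test_fraction` share of them); all remaining rows, synthetic
#' included, train the models.
#'
#' @param data Feature table with target (typically post-augmentation).
#' @param models Named list of model recipes ([surrogate_spec()] or
#'   `"gbt"`/`"mlr"`/`"svr"` strings). Default: the boosted surrogate only.
#' @param spec An [eval_spec()].
#' @param features,target Column names.
#' @param seed Integer seed; split s uses a derived substream.
#' @return An `evaluation_report`: list with `metrics` (tibble: split, model,
#'   r2, cov) and `summary` (tibble: model, metric, min, mean, max).
#' @export
evaluate_robustness <- function(data, models = list(gbt = surrogate_spec()),
                                spec = eval_spec(),
                                features = default_features(), target = "ts",
                                seed = NULL) {
  stopifnot(inherits(spec, "eval_spec"))
  if (is.null(names(models)) || any(names(models) == "")) {
    stop_stressaug("`models` must be a fully named list.", "spec")
  }
  data <- validate_feature_table(data, features = features, target = target,
                                 require_target = TRUE)
  n <- nrow(data)
  pool <- if (spec$test_originals_only && "provenance" %in% names(data)) {
    which(data$provenance == "original")
  } else {
    seq_len(n)
  }
  n_test <- max(2L, as.integer(round(spec$test_fraction * length(pool))))
  if (length(pool) - n_test < 2 || n - n_test < 2) {
    stop_stressaug("Table too small for the requested test fraction.", "too_few_rows")
  }
  fitters <- lapply(models, resolve_model)

  rows <- vector("list", spec$n_splits)
  for (s in seq_len(spec$n_splits)) {
    split_seed <- if (is.null(seed)) NULL else stage_seed(seed, paste0("split", s))
    test <- with_seed(split_seed, sample(pool, n_test))
    train <- data[-test, , drop = FALSE]
    y_test <- data[[target]][test]
    rows[[s]] <- purrr::imap(fitters, function(fitter, name) {
      fit <- fitter(train, features, target, split_seed)
      yhat <- predict(fit, data[test, , drop = FALSE])
      tibble::tibble(split = s, model = name,
                     r2 = r2_score(y_test, yhat),
                     cov = coverage(y_test, yhat))
    }) |> dplyr::bind_rows()
  }
  metrics <- dplyr::bind_rows(rows)
  summary <- metrics |>
    tidyr::pivot_longer(c("r2", "cov"), names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::summarise(min = min(.data$value), mean = mean(.data$value),
                     max = max(.data$value), .groups = "drop")
  structure(list(metrics = metrics, summary = summary, spec = spec,
                 n = n, n_test = n_test),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Robustness evaluation:", x$spec$n_splits, "random splits,",
      x$n_test, "test rows per split\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$metrics

#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = c("metric"),
                       values_from = c("min", "mean", "max"),
                       names_glue = "{metric}_{.value}")
}

#' @rdname autoplot.stressaug
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, c("r2", "cov"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$model)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7, position = "identity") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = "metric value per split", y = "splits",
                  title = "Repeated random-split robustness") +
    ggplot2::theme_minimal()
}
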