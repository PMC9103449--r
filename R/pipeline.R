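#' Full-pipeline configuration
#'
#' Bundles the per-stage settings with one global seed that is split
#' deterministically into per-stage substreams, so any stage can be re-run in
#' isolation and reproduce the pipeline's draws. All defaults are the
#' framework's operating point: NNI with lambda 0.1 and 20 points per sample,
#' K = 2 imbalance detection with boundary SMOTE, the 55/0.16/8/120 boosted
#' surrogate, and 999 random splits for robustness.
#'
#' @param seed Non-negative integer global seed.
#' @param augmentation List of [augment_nni()] settings: `lambda`,
#'   `points_per_sample`, `label_rule`, `knn_k`, `clamp_nonnegative`.
#' @param smote List of [smote_augment()] settings plus `enabled` and `k`.
#' @param surrogate A [surrogate_spec()].
#' @param tune Run [tune_surrogate()] before fitting?
#' @param evaluation An [eval_spec()].
#' @param surface List: `eps_nh_fixed`, `n_grid`.
#' @param features,target Column names.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            augmentation = list(lambda = 0.1,
                                                points_per_sample = 20,
                                                label_rule = "inherit_parent",
                                                knn_k = 3,
                                                clamp_nonnegative = FALSE),
                            smote = list(enabled = TRUE, k = 2,
                                         k_neighbors = 5, m_neighbors = 10,
                                         target_ratio = 1,
                                         interpolate_target = TRUE),
                            surrogate = surrogate_spec(),
                            tune = FALSE,
                            evaluation = eval_spec(),
                            surface = list(eps_nh_fixed = 0.38, n_grid = 200),
                            features = default_features(), target = "ts") {
  if (is.null(seed) || seed < 0) stop_stressaug("`seed` must be >= 0.", "spec")
  stopifnot(inherits(surrogate, "surrogate_spec"), inherits(evaluation, "eval_spec"))
  structure(
    list(seed = as.integer(seed), augmentation = augmentation, smote = smote,
         surrogate = surrogate, tune = tune, evaluation = evaluation,
         surface = surface, features = features, target = target),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    abort(paste0("Pipeline stage '", stage, "' failed: ", conditionMessage(e)),
          class = c("stressaug_error_stage", "stressaug_error"), parent = e)
  })
}

#' Run the full augmentation-surrogate pipeline
#'
#' Executes the stages in order: NNI augmentation, K-means imbalance
#' detection + boundary SMOTE, (optional) learning-curve tuning, surrogate
#' fit, repeated-split robustness evaluation, Shapley attribution of the
#' original rows, and response-surface prediction. A run log records the seed
#' and row count at every stage. When `outdir` is given, every artifact is
#' written there (CSV tables, text summaries).
#'
#' @param data Input feature table (or a CSV path).
#' @param config A [pipeline_config()].
#' @param outdir Output directory, or `NULL` to skip writing.
#' @return A `pipeline_result`: list with `data` (augmented table), `model`,
#'   `tuning` (or NULL), `report` ([evaluate_robustness()] result),
#'   `attribution`, `surface`, and `log` (tibble).
#' @export
run_pipeline <- function(data, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  features <- config$features
  target <- config$target
  log <- list()
  note <- function(stage, rows, seed) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, rows = rows, seed = if (is.null(seed)) NA_integer_ else seed)
  }

  if (is.character(data)) {
    data <- run_stage("read", read_feature_table(data, features = features,
                                                 target = target))
  }
  data <- run_stage("validate",
                    validate_feature_table(data, features = features,
                                           target = target, require_target = TRUE))
  note("input", nrow(data), config$seed)

  aug <- config$augmentation
  s_nni <- stage_seed(config$seed, "nni")
  data_aug <- run_stage("nni", augment_nni(
    data, lambda = aug$lambda, points_per_sample = aug$points_per_sample,
    label_rule = aug$label_rule, knn_k = aug$knn_k,
    clamp_nonnegative = isTRUE(aug$clamp_nonnegative),
    features = features, target = target, seed = s_nni))
  note("nni", nrow(data_aug), s_nni)

  if (isTRUE(config$smote$enabled)) {
    sm <- config$smote
    s_bal <- stage_seed(config$seed, "balance")
    data_aug <- run_stage("smote", balance_smote(
      data_aug, k = sm$k, k_neighbors = sm$k_neighbors,
      m_neighbors = sm$m_neighbors, target_ratio = sm$target_ratio,
      interpolate_target = isTRUE(sm$interpolate_target),
      features = features, target = target, seed = s_bal))
    note("smote", nrow(data_aug), s_bal)
  }

  tuning <- NULL
  spec <- config$surrogate
  if (isTRUE(config$tune)) {
    s_tune <- stage_seed(config$seed, "tune")
    tuning <- run_stage("tune", tune_surrogate(
      data_aug, start = spec, features = features, target = target,
      seed = s_tune))
    spec <- tuning$spec
    note("tune", nrow(data_aug), s_tune)
  }

  s_fit <- stage_seed(config$seed, "fit")
  model <- run_stage("fit", fit_surrogate(data_aug, spec, features = features,
                                          target = target, seed = s_fit))
  note("fit", nrow(data_aug), s_fit)

  s_eval <- stage_seed(config$seed, "evaluate")
  report <- run_stage("evaluate", evaluate_robustness(
    data_aug, models = list(gbt = spec), spec = config$evaluation,
    features = features, target = target, seed = s_eval))
  note("evaluate", nrow(data_aug), s_eval)

  originals <- data_aug[data_aug$provenance == "original", , drop = FALSE]
  attribution <- run_stage("explain", exact_shapley(model, originals))
  note("explain", nrow(originals), NA_integer_)

  surface <- run_stage("surface", predict_surface(
    model, eps_nh_fixed = config$surface$eps_nh_fixed,
    n_grid = config$surface$n_grid))
  note("surface", length(surface$eps_h) * length(surface$omega), NA_integer_)

  result <- structure(
    list(data = data_aug, model = model, tuning = tuning, report = report,
         attribution = attribution, surface = surface,
         log = dplyr::bind_rows(log), config = config),
    class = "pipeline_result"
  )
  if (!is.null(outdir)) write_pipeline_result(result, outdir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ")\n")
  print(as.data.frame(x$log), row.names = FALSE)
  print(x$report)
  print(x$attribution)
  invisible(x)
}

write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  write_feature_table(result$data, file.path(outdir, "augmented.csv"),
                      features = cfg$features, target = cfg$target)
  readr::write_csv(result$report$metrics, file.path(outdir, "evaluation_splits.csv"),
                   progress = FALSE)
  readr::write_csv(result$report$summary, file.path(outdir, "evaluation_summary.csv"),
                   progress = FALSE)
  readr::write_csv(result$attribution$importance, file.path(outdir, "importance.csv"),
                   progress = FALSE)
  phi <- result$attribution$phi
  readr::write_csv(phi, file.path(outdir, "shapley_values.csv"), progress = FALSE)
  readr::write_csv(tidy(result$surface), file.path(outdir, "surface.csv"),
                   progress = FALSE)
  readr::write_csv(result$log, file.path(outdir, "run_log.csv"), progress = FALSE)
  if (!is.null(result$tuning)) {
    readr::write_csv(result$tuning$trace, file.path(outdir, "tuning_trace.csv"),
                     progress = FALSE)
  }
  summary_lines <- c(
    paste0("seed: ", cfg$seed),
    paste0("rows_after_augmentation: ", nrow(result$data)),
    paste0("surrogate: n_trees=", result$model$spec$n_trees,
           " eta=", result$model$spec$eta,
           " max_depth=", result$model$spec$max_depth,
           " reg_lambda=", result$model$spec$reg_lambda),
    utils::capture.output(print(as.data.frame(result$report$summary),
                                row.names = FALSE)),
    utils::capture.output(print(as.data.frame(result$attribution$importance),
                                row.names = FALSE))
  )
  writeLines(summary_lines, file.path(outdir, "summary.txt"))
  invisible(result)
}
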