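#' Hyperparameters of the gradient-boosted surrogate
#'
#' Defaults are the tuned operating point for the tensile-stress surrogate:
#' 55 trees, learning rate 0.16, maximum depth 8, L2 leaf regularization 120.
#' All remaining boosting options are pinned to a minimal deterministic
#' configuration: squared-error objective, no row or column subsampling,
#' minimum child weight 1, single thread.
#'
#' @param n_trees Number of boosting rounds (>= 1).
#' @param eta Learning rate in (0, 1].
#' @param max_depth Maximum tree depth (>= 1).
#' @param reg_lambda L2 regularization on leaf weights (>= 0).
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(n_trees = 55, eta = 0.16, max_depth = 8,
                           reg_lambda = 120) {
  if (n_trees < 1) stop_stressaug("`n_trees` must be >= 1.", "spec")
  if (eta <= 0 || eta > 1) stop_stressaug("`eta` must be in (0, 1].", "spec")
  if (max_depth < 1) stop_stressaug("`max_depth` must be >= 1.", "spec")
  if (reg_lambda < 0) stop_stressaug("`reg_lambda` must be >= 0.", "spec")
  structure(list(n_trees = as.integer(n_trees), eta = eta,
                 max_depth = as.integer(max_depth), reg_lambda = reg_lambda),
            class = "surrogate_spec")
}

new_md_surrogate <- function(kind, fit, spec, features, target, n, seed,
                             extra = list()) {
  structure(
    c(list(kind = kind, fit = fit, spec = spec, features = features,
           target = target, n = n, seed = seed), extra),
    class = "md_surrogate"
  )
}

#' Fit the gradient-boosted tree surrogate
#'
#' Squared-error gradient boosting with L2 leaf regularization on the raw
#' (unstandardized) features; deterministic given the data, spec and seed.
#' The base score is pinned to the training-target mean.
#'
#' @param data Feature table with target.
#' @param spec A [surrogate_spec()].
#' @param features,target Column names.
#' @param seed Integer seed.
#' @return An object of class `md_surrogate` (kind `"gbt"`).
#' @export
fit_surrogate <- function(data, spec = surrogate_spec(),
                          features = default_features(), target = "ts",
                          seed = NULL) {
  stopifnot(inherits(spec, "surrogate_spec"))
  data <- validate_feature_table(data, features = features, target = target,
                                 require_target = TRUE)
  if (nrow(data) < 2) stop_stressaug("Need at least 2 rows to fit.", "too_few_rows")
  X <- as.matrix(data[, features])
  y <- data[[target]]
  params <- list(
    objective = "reg:squarederror",
    eta = spec$eta,
    max_depth = spec$max_depth,
    lambda = spec$reg_lambda,
    subsample = 1, colsample_bytree = 1, min_child_weight = 1,
    nthread = 1,
    base_score = mean(y),
    seed = if (is.null(seed)) 0L else as.integer(seed)
  )
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = spec$n_trees, verbose = 0
  )
  new_md_surrogate("gbt", booster, spec, features, target, nrow(data), seed,
                   extra = list(envelope = apply(X, 2, range)))
}

#' Fit a comparison baseline
#'
#' `mlr` is ordinary least squares with intercept, solved in closed form; a
#' rank-deficient design falls back to the minimum-norm solution (with a
#' message). `svr` is epsilon-insensitive support-vector regression with a
#' radial-basis kernel on z-scored features (cost 1, epsilon 0.1, kernel
#' width 1/d on the standardized scale).
#'
#' @param data Feature table with target.
#' @param kind `"mlr"` or `"svr"`.
#' @param features,target Column names.
#' @param seed Integer seed (kept for interface symmetry; both fits are
#'   deterministic).
#' @return An `md_surrogate` of the requested kind.
#' @export
fit_baseline <- function(data, kind = c("mlr", "svr"),
                         features = default_features(), target = "ts",
                         seed = NULL) {
  kind <- match.arg(kind)
  data <- validate_feature_table(data, features = features, target = target,
                                 require_target = TRUE)
  X <- as.matrix(data[, features])
  y <- data[[target]]
  fit <- if (kind == "mlr") {
    Xd <- cbind(`(Intercept)` = 1, X)
    qrX <- qr(Xd)
    if (qrX$rank < ncol(Xd)) {
      inform("Singular design; returning the minimum-norm least-squares solution.")
      coef <- drop(MASS::ginv(Xd) %*% y)
      names(coef) <- colnames(Xd)
    } else {
      coef <- drop(qr.coef(qrX, y))
    }
    list(coef = coef)
  } else {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
    svm_fit <- e1071::svm(x = Xs, y = y, type = "eps-regression",
                          kernel = "radial", cost = 1, epsilon = 0.1,
                          gamma = 1 / ncol(X), scale = FALSE, fitted = FALSE)
    # a target entirely inside the epsilon tube leaves no support vectors;
    # the fit degenerates to the constant mean
    if (svm_fit$tot.nSV == 0) {
      list(constant = mean(y), center = ctr, scale = scl)
    } else {
      list(svm = svm_fit, center = ctr, scale = scl)
    }
  }
  new_md_surrogate(kind, fit, NULL, features, target, nrow(data), seed,
                   extra = list(envelope = apply(X, 2, range)))
}

#' Predict from a fitted surrogate or baseline
#'
#' @param object An `md_surrogate`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted tensile stress.
#' @export
predict.md_surrogate <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0) {
    stop_stressaug(paste0("`newdata` lacks feature column(s): ",
                          paste(missing_cols, collapse = ", ")), "missing_feature")
  }
  X <- as.matrix(tibble::as_tibble(newdata)[, object$features])
  storage.mode(X) <- "double"
  switch(object$kind,
    gbt = predict(object$fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    mlr = drop(cbind(1, X) %*% object$fit$coef),
    svr = {
      if (!is.null(object$fit$constant)) {
        rep(object$fit$constant, nrow(X))
      } else {
        Xs <- sweep(sweep(X, 2, object$fit$center), 2, object$fit$scale, `/`)
        as.numeric(predict(object$fit$svm, Xs))
      }
    }
  )
}

#' @export
print.md_surrogate <- function(x, ...) {
  cat("Surrogate model [", x$kind, "] fitted on ", x$n, " rows, features: ",
      paste(x$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy md_surrogate
#' @export
tidy.md_surrogate <- function(x, ...) {
  if (x$kind == "mlr") {
    tibble::tibble(term = names(x$fit$coef), estimate = unname(x$fit$coef))
  } else if (x$kind == "gbt") {
    imp <- xgboost::xgb.importance(model = x$fit)
    out <- tibble::tibble(term = x$features, gain = 0)
    out$gain[match(imp$Feature, x$features)] <- imp$Gain
    out
  } else {
    tibble::tibble(term = "support_vectors", estimate = x$fit$svm$tot.nSV)
  }
}

#' @method glance md_surrogate
#' @export
glance.md_surrogate <- function(x, ...) {
  tibble::tibble(kind = x$kind, n = x$n, d = length(x$features))
}

resolve_model <- function(model) {
  # a model recipe is either a surrogate_spec (gbt) or a baseline kind string
  if (inherits(model, "surrogate_spec")) {
    function(data, features, target, seed) {
      fit_surrogate(data, model, features = features, target = target, seed = seed)
    }
  } else if (is.character(model) && model %in% c("mlr", "svr")) {
    function(data, features, target, seed) {
      fit_baseline(data, model, features = features, target = target, seed = seed)
    }
  } else if (is.character(model) && model == "gbt") {
    function(data, features, target, seed) {
      fit_surrogate(data, surrogate_spec(), features = features,
                    target = target, seed = seed)
    }
  } else {
    stop_stressaug("`model` must be a surrogate_spec or one of 'gbt', 'mlr', 'svr'.",
                   "spec")
  }
}

#' Cross-validated R-squared
#'
#' Randomly partitions the rows into `folds` near-equal groups, holds each
#' out once, fits the model recipe on the remainder, and returns the mean of
#' the per-fold out-of-sample R-squared. Singleton test folds are rejected
#' (R-squared is undefined on one observation), so `folds` may be at most
#' `n/2`.
#'
#' @param data Feature table with target.
#' @param model A [surrogate_spec()] or one of `"gbt"`, `"mlr"`, `"svr"`.
#' @param folds Number of folds (default 10).
#' @param features,target Column names.
#' @param seed Integer seed for the partition.
#' @return Mean out-of-fold R-squared (scalar).
#' @export
cv_score <- function(data, model = surrogate_spec(), folds = 10,
                     features = default_features(), target = "ts",
                     seed = NULL) {
  data <- validate_feature_table(data, features = features, target = target,
                                 require_target = TRUE)
  n <- nrow(data)
  if (folds < 2) stop_stressaug("`folds` must be >= 2.", "spec")
  if (n < folds) stop_stressaug("Fewer rows than folds.", "too_few_rows")
  if (n < 2 * folds) {
    stop_stressaug("Each test fold must hold at least 2 rows; reduce `folds`.",
                   "singleton_fold")
  }
  fitter <- resolve_model(model)
  assign_fold <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  scores <- vapply(seq_len(folds), function(f) {
    test <- which(assign_fold == f)
    fit <- fitter(data[-test, , drop = FALSE], features, target, seed)
    r2_score(data[[target]][test], predict(fit, data[test, , drop = FALSE]))
  }, numeric(1))
  mean(scores)
}

#' Default learning-curve grids
#'
#' One grid per boosted-tree hyperparameter, swept coordinate-wise by
#' [tune_surrogate()]: tree count 1..100 (step 5 plus the endpoints),
#' learning rate 0.10..0.30 (step 0.02), depth 3..15, and L2 regularization
#' \{0, 1, 10, 60, 120, 240\}.
#'
#' @return Named list of numeric grids.
#' @export
default_tuning_grids <- function() {
  list(
    n_trees = sort(unique(c(1, seq(5, 100, by = 5)))),
    eta = seq(0.10, 0.30, by = 0.02),
    max_depth = 3:15,
    reg_lambda = c(0, 1, 10, 60, 120, 240)
  )
}

#' Coordinate-wise learning-curve tuning
#'
#' Sweeps each hyperparameter grid in the fixed order n_trees, eta,
#' max_depth, reg_lambda, holding the others at their current values and
#' keeping the argmax of the 10-fold cross-validated R-squared; ties break
#' toward the smaller (more regular) value. The same fold seed is used for
#' every candidate so scores along a curve are comparable.
#'
#' @param data Feature table with target.
#' @param grids Named list of grids (subset of the four names above).
#' @param start Starting [surrogate_spec()].
#' @param folds CV folds (default 10).
#' @param features,target Column names.
#' @param seed Integer seed (folds).
#' @return List with `spec` (the tuned [surrogate_spec()]) and `trace`
#'   (tibble: parameter, value, score — one row per grid point evaluated).
#' @export
tune_surrogate <- function(data, grids = default_tuning_grids(),
                           start = surrogate_spec(), folds = 10,
                           features = default_features(), target = "ts",
                           seed = NULL) {
  order_names <- c("n_trees", "eta", "max_depth", "reg_lambda")
  if (length(grids) == 0 || !all(names(grids) %in% order_names)) {
    stop_stressaug("`grids` must be a non-empty named list over n_trees, eta, max_depth, reg_lambda.",
                   "spec")
  }
  current <- unclass(start)[order_names]
  trace <- list()
  for (par in intersect(order_names, names(grids))) {
    grid <- sort(grids[[par]])
    scores <- vapply(grid, function(v) {
      cand <- current
      cand[[par]] <- v
      spec <- surrogate_spec(cand$n_trees, cand$eta, cand$max_depth,
                             cand$reg_lambda)
      cv_score(data, spec, folds = folds, features = features,
               target = target, seed = seed)
    }, numeric(1))
    best <- grid[which.max(scores)]  # grid sorted: ties resolve to smaller value
    current[[par]] <- best
    trace[[par]] <- tibble::tibble(parameter = par, value = grid, score = scores)
  }
  list(
    spec = surrogate_spec(current$n_trees, current$eta, current$max_depth,
                          current$reg_lambda),
    trace = dplyr::bind_rows(trace)
  )
}
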