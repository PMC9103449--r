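#' Exact Shapley attribution by coalition enumeration
#'
#' Computes interventional Shapley values exactly: for feature j,
#' `phi_j = sum over S not containing j of |S|!(d-|S|-1)!/d! * (v(S+j) - v(S))`
#' where `v(S)` is the model prediction averaged over the background rows
#' after replacing the features in S with the explained row's values
#' (marginal expectation over the empirical background distribution). All
#' `2^d` coalitions are enumerated, which is affordable for the small feature
#' spaces this package targets (guard: d <= 12; here d = 3, 8 coalitions).
#'
#' Satisfies local accuracy by construction: `base_value + sum_j phi_ij`
#' equals the model prediction at row i, where `base_value` is the mean
#' background prediction.
#'
#' @param object An `md_surrogate`, or a function mapping a feature data
#'   frame to a numeric prediction vector.
#' @param data Rows to explain (data frame with the feature columns).
#' @param background Background table for the marginal expectation; defaults
#'   to `data` itself.
#' @param features Feature column names.
#' @return A `shap_attribution`: list with `phi` (tibble, one attribution
#'   column per feature), `base_value`, `prediction` (per explained row) and
#'   `importance` (tibble of mean |phi| per feature, descending; ties keep
#'   column order).
#' @export
exact_shapley <- function(object, data, background = data,
                          features = default_features()) {
  predict_fn <- if (inherits(object, "md_surrogate")) {
    features <- object$features
    function(df) predict(object, df)
  } else if (is.function(object)) {
    object
  } else {
    stop_stressaug("`object` must be an md_surrogate or a prediction function.", "spec")
  }
  d <- length(features)
  if (d > 12) stop_stressaug("Exact enumeration is guarded at d <= 12 features.", "too_many_features")
  data <- validate_feature_table(data, features = features)
  background <- validate_feature_table(background, features = features)
  n <- nrow(data)
  nb <- nrow(background)
  X <- as.matrix(data[, features])
  B <- as.matrix(background[, features])

  # v[[coalition]] : length-n vector of mean background predictions with the
  # coalition's features swapped in from the explained row
  subsets <- lapply(0:(2^d - 1), function(bits) which(bitwAnd(bits, 2^(0:(d - 1))) > 0))
  key <- vapply(subsets, function(s) paste(s, collapse = ","), character(1))
  v <- matrix(NA_real_, n, length(subsets), dimnames = list(NULL, key))
  for (si in seq_along(subsets)) {
    s <- subsets[[si]]
    # stack: for each explained row, the full background with columns s replaced
    M <- B[rep(seq_len(nb), times = n), , drop = FALSE]
    if (length(s) > 0) {
      M[, s] <- X[rep(seq_len(n), each = nb), s, drop = FALSE]
    }
    df <- tibble::as_tibble(as.data.frame(M))
    names(df) <- features
    pred <- predict_fn(df)
    v[, si] <- colMeans(matrix(pred, nb, n))
  }

  fact <- factorial(0:d)
  phi <- matrix(0, n, d, dimnames = list(NULL, features))
  for (j in seq_len(d)) {
    for (si in seq_along(subsets)) {
      s <- subsets[[si]]
      if (j %in% s) next
      w <- fact[length(s) + 1] * fact[d - length(s)] / fact[d + 1]
      s_with <- paste(sort(c(s, j)), collapse = ",")
      phi[, j] <- phi[, j] + w * (v[, s_with] - v[, si])
    }
  }
  base_value <- v[1, "" == key][1]
  prediction <- v[, key == paste(seq_len(d), collapse = ",")]
  mean_abs <- colMeans(abs(phi))
  ord <- order(-mean_abs, seq_len(d))
  structure(
    list(
      phi = tibble::as_tibble(as.data.frame(phi)),
      base_value = unname(base_value),
      prediction = unname(prediction),
      importance = tibble::tibble(feature = features[ord],
                                  mean_abs_shap = unname(mean_abs[ord]))
    ),
    class = "shap_attribution"
  )
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat("Exact Shapley attribution over", nrow(x$phi), "rows; base value",
      signif(x$base_value, 6), "\n")
  print(as.data.frame(x$importance), row.names = FALSE)
  invisible(x)
}

#' @method tidy shap_attribution
#' @export
tidy.shap_attribution <- function(x, ...) {
  phi <- x$phi
  phi$row <- seq_len(nrow(phi))
  tidyr::pivot_longer(phi, -"row", names_to = "feature", values_to = "shap")
}

#' @method glance shap_attribution
#' @export
glance.shap_attribution <- function(x, ...) {
  tidyr::pivot_wider(x$importance, names_from = "feature",
                     values_from = "mean_abs_shap")
}

#' Global feature importance ranking
#'
#' Applies [exact_shapley()] to every row of `data` with `data` itself as the
#' background and ranks features by descending mean absolute attribution
#' (ties keep column order).
#'
#' @param model An `md_surrogate`.
#' @param data Feature table to explain.
#' @return Tibble with columns `feature`, `mean_abs_shap`, ordered by
#'   importance.
#' @export
importance_ranking <- function(model, data) {
  exact_shapley(model, data)$importance
}

#' @rdname autoplot.stressaug
#' @method autoplot shap_attribution
#' @export
autoplot.shap_attribution <- function(object, ...) {
  imp <- object$importance
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$mean_abs_shap, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |Shapley value| (MPa)", y = NULL,
                  title = "Global feature importance") +
    ggplot2::theme_minimal()
}

#' Dense response surface at fixed non-hydrogen-bond strength
#'
#' Evaluates the fitted surrogate on the Cartesian grid of an `eps_h` axis
#' and an `omega` axis with `eps_nh` held fixed (default 0.38 kcal/mol, the
#' background non-bonded interaction strength). Default axes span the model's
#' training envelope with 200 points each; a warning is raised when a
#' requested axis leaves the envelope (extrapolation).
#'
#' @param model An `md_surrogate` fitted on (omega, eps_h, eps_nh).
#' @param eps_h,omega Strictly increasing axis vectors; default 200 points
#'   over the training range.
#' @param eps_nh_fixed Fixed non-hydrogen-bond strength (default 0.38).
#' @param n_grid Axis length when defaults are used.
#' @return A `surface_grid`: list with the axes, the fixed value and the
#'   prediction matrix `ts` (rows = eps_h, columns = omega).
#' @export
predict_surface <- function(model, eps_h = NULL, omega = NULL,
                            eps_nh_fixed = 0.38, n_grid = 200) {
  stopifnot(inherits(model, "md_surrogate"))
  env <- model$envelope
  if (is.null(eps_h)) eps_h <- seq(env[1, "eps_h"], env[2, "eps_h"], length.out = n_grid)
  if (is.null(omega)) omega <- seq(env[1, "omega"], env[2, "omega"], length.out = n_grid)
  if (any(diff(eps_h) <= 0) || any(diff(omega) <= 0)) {
    stop_stressaug("Axes must be strictly increasing.", "axes")
  }
  outside <- eps_h[1] < env[1, "eps_h"] || eps_h[length(eps_h)] > env[2, "eps_h"] ||
    omega[1] < env[1, "omega"] || omega[length(omega)] > env[2, "omega"] ||
    eps_nh_fixed < env[1, "eps_nh"] || eps_nh_fixed > env[2, "eps_nh"]
  if (outside) {
    warn("Requested grid extends beyond the training envelope; predictions are extrapolations.")
  }
  grid <- tidyr::expand_grid(eps_h = eps_h, omega = omega)
  grid$eps_nh <- eps_nh_fixed
  pred <- predict(model, grid)
  ts <- matrix(pred, nrow = length(eps_h), ncol = length(omega), byrow = TRUE)
  structure(list(eps_h = eps_h, omega = omega, eps_nh_fixed = eps_nh_fixed,
                 ts = ts),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat("Response surface:", length(x$eps_h), "x", length(x$omega),
      "grid at eps_nh =", x$eps_nh_fixed, "| TS range",
      paste(signif(range(x$ts), 5), collapse = " .. "), "MPa\n")
  invisible(x)
}

#' Long-format view of a surface grid
#'
#' @param x A `surface_grid`.
#' @param ... Unused.
#' @return Tibble with columns `eps_h`, `omega`, `ts`.
#' @method tidy surface_grid
#' @export
tidy.surface_grid <- function(x, ...) {
  tidyr::expand_grid(eps_h = x$eps_h, omega = x$omega) |>
    dplyr::mutate(ts = as.vector(t(x$ts)))
}

#' Plot methods for stressaug result objects
#'
#' `autoplot()` methods: histograms of per-split metrics for an
#' `evaluation_report`, a bar chart of mean |Shapley value| for a
#' `shap_attribution`, and a filled-contour map for a `surface_grid`.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot.stressaug
NULL

#' @rdname autoplot.stressaug
#' @method autoplot surface_grid
#' @export
autoplot.surface_grid <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$eps_h, y = .data$omega,
                                     fill = .data$ts)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "TS (MPa)") +
    ggplot2::labs(x = "hydrogen-bond strength (kcal/mol)",
                  y = "phospholipid + protein mass fraction",
                  title = paste0("Predicted tensile stress at eps_nh = ",
                                 object$eps_nh_fixed)) +
    ggplot2::theme_minimal()
}
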