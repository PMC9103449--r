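#' Per-feature interpolation variance
#'
#' The Gaussian neighbourhood used by NNI augmentation has, for feature j,
#' mean equal to the parent sample's value and variance
#' `sigma2_j = (lambda / m) * sum_i x_ij`, i.e. lambda times the feature mean
#' over the m original rows. The variance is computed once from the original
#' rows and never updated as synthetics accumulate.
#'
#' A feature whose mean is negative would yield a negative variance; this is
#' an error rather than a silent absolute value, since the parameterisation
#' presumes non-negative feature scales.
#'
#' @param data Feature table; only rows tagged `original` enter the sums
#'   (all rows when no `provenance` column exists).
#' @param lambda Non-negative interpolation parameter (default 0.1).
#' @param features Feature column names.
#' @return Named numeric vector of per-feature variances.
#' @export
feature_variance <- function(data, lambda = 0.1, features = default_features()) {
  if (lambda < 0) stop_stressaug("`lambda` must be non-negative.", "spec")
  data <- validate_feature_table(data, features = features)
  if ("provenance" %in% names(data)) {
    data <- dplyr::filter(data, .data$provenance == "original")
  }
  if (nrow(data) < 1) stop_stressaug("No original rows to compute variances from.", "empty")
  mu <- vapply(features, function(f) mean(data[[f]]), numeric(1))
  if (any(mu < 0)) {
    neg <- features[mu < 0]
    stop_stressaug(
      paste0("Feature mean is negative for: ", paste(neg, collapse = ", "),
             "; the interpolation variance lambda * mean(x_j) requires non-negative feature scales."),
      "negative_mean"
    )
  }
  lambda * mu
}

#' Augment a table by nearest-neighbor Gaussian interpolation
#'
#' For each of the m original rows, draws `points_per_sample` synthetic rows
#' whose feature j is Normal(x_ij, sigma2_j) with sigma2_j from
#' [feature_variance()]. The output holds the m originals first (bit-exact),
#' followed by each parent's synthetics in parent order, for
#' `m * (points_per_sample + 1)` rows in total.
#'
#' Targets for synthetic rows follow `label_rule`:
#' \describe{
#'   \item{`inherit_parent`}{copy the parent's target — each synthetic lives
#'     in its parent's neighbourhood (the default).}
#'   \item{`knn_idw`}{inverse-distance-weighted mean of the `knn_k` nearest
#'     original rows' targets in z-score standardized feature space (parent
#'     included; a zero distance returns that row's target).}
#' }
#'
#' Features are not clipped to physical ranges (the Gaussian neighbourhood is
#' unbounded); set `clamp_nonnegative = TRUE` to floor features at zero for
#' physically non-negative columns.
#'
#' @param data Feature table with target present.
#' @param lambda Interpolation parameter (default 0.1).
#' @param points_per_sample Synthetics per original row (default 20).
#' @param label_rule `"inherit_parent"` or `"knn_idw"`.
#' @param knn_k Neighbour count for `knn_idw` (default 3).
#' @param clamp_nonnegative Floor synthetic features at 0?
#' @param features,target Column names.
#' @param seed Integer seed.
#' @return Tibble with `m * (points_per_sample + 1)` rows and a `provenance`
#'   column tagging synthetics as `"nni"`.
#' @export
augment_nni <- function(data, lambda = 0.1, points_per_sample = 20,
                        label_rule = c("inherit_parent", "knn_idw"),
                        knn_k = 3, clamp_nonnegative = FALSE,
                        features = default_features(), target = "ts",
                        seed = NULL) {
  label_rule <- match.arg(label_rule)
  if (points_per_sample < 0) stop_stressaug("`points_per_sample` must be >= 0.", "spec")
  if (knn_k < 1) stop_stressaug("`knn_k` must be >= 1.", "spec")
  data <- validate_feature_table(data, features = features, target = target,
                                 require_target = TRUE)
  if (!"provenance" %in% names(data)) data$provenance <- rep("original", nrow(data))
  originals <- dplyr::filter(data, .data$provenance == "original")
  m <- nrow(originals)
  k <- as.integer(points_per_sample)
  if (k == 0) return(data)

  sigma2 <- feature_variance(originals, lambda = lambda, features = features)
  sigma <- sqrt(sigma2)

  X <- as.matrix(originals[, features])
  synth <- with_seed(seed, {
    # parent-major block: rows (i-1)*k + 1 .. i*k belong to parent i
    parent <- rep(seq_len(m), each = k)
    noise <- matrix(rnorm(m * k * length(features)), m * k, length(features))
    S <- X[parent, , drop = FALSE] + sweep(noise, 2, sigma, `*`)
    if (clamp_nonnegative) S[S < 0] <- 0
    out <- tibble::as_tibble(as.data.frame(S))
    names(out) <- features
    out[[target]] <- switch(
      label_rule,
      inherit_parent = originals[[target]][parent],
      knn_idw = knn_idw_labels(S, X, originals[[target]], knn_k)
    )
    out$provenance <- rep("nni", nrow(out))
    out
  })
  dplyr::bind_rows(data, synth)
}

# Inverse-distance-weighted target over the knn_k nearest originals in
# z-scored feature space; exact hits take that row's target.
knn_idw_labels <- function(S, X, y, knn_k) {
  knn_k <- min(knn_k, nrow(X))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  Ss <- sweep(sweep(S, 2, ctr), 2, scl, `/`)
  vapply(seq_len(nrow(Ss)), function(i) {
    d <- sqrt(colSums((t(Xs) - Ss[i, ])^2))
    nn <- order(d)[seq_len(knn_k)]
    dn <- d[nn]
    if (any(dn == 0)) return(mean(y[nn[dn == 0]]))
    w <- 1 / dn
    sum(w * y[nn]) / sum(w)
  }, numeric(1))
}
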