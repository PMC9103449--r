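#' K-means clustering of the feature space
#'
#' Clusters the z-score standardized features with Lloyd's algorithm (best of
#' 10 random restarts by within-cluster sum of squares, up to 300 iterations).
#' Zero-variance features pass through centered but unscaled. Used to detect
#' sample imbalance before boundary oversampling.
#'
#' @param data Feature table.
#' @param k Number of clusters (default 2).
#' @param features Feature column names.
#' @param seed Integer seed (restarts are random).
#' @return A `cluster_assignment`: list with `k`, integer `labels` (1..k),
#'   `centroids` (k x d, standardized space), `sizes`, and the
#'   standardization (`center`, `scale`) used.
#' @export
cluster_features <- function(data, k = 2, features = default_features(),
                             seed = NULL) {
  data <- validate_feature_table(data, features = features)
  n <- nrow(data)
  if (n < k) stop_stressaug("Fewer rows than clusters.", "too_few_rows")
  X <- as.matrix(data[, features])
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  fit <- with_seed(seed, {
    if (k == 1) {
      list(cluster = rep(1L, n), centers = matrix(colMeans(Xs), 1,
                                                  dimnames = list(NULL, features)))
    } else {
      kmeans(Xs, centers = k, iter.max = 300, nstart = 10, algorithm = "Lloyd")
    }
  })
  labels <- as.integer(fit$cluster)
  structure(
    list(k = k, labels = labels, centroids = fit$centers,
         sizes = tabulate(labels, nbins = k), center = ctr, scale = scl,
         features = features),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("K-means assignment: k =", x$k, "| sizes:", paste(x$sizes, collapse = "/"), "\n")
  invisible(x)
}

#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble::tibble(row = seq_along(x$labels), cluster = x$labels)
}

#' @method glance cluster_assignment
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels),
                 minority_size = min(x$sizes), majority_size = max(x$sizes))
}

standardize_with <- function(data, assignment) {
  X <- as.matrix(data[, assignment$features])
  sweep(sweep(X, 2, assignment$center), 2, assignment$scale, `/`)
}

minority_cluster <- function(assignment) {
  # smaller cluster; ties broken toward the lower cluster index
  which.min(assignment$sizes)
}

#' Borderline (danger) minority rows
#'
#' Classifies each minority-cluster row by the cluster composition of its
#' `m_neighbors` nearest rows (standardized Euclidean distance, self
#' excluded), with the minority cluster as the positive class and majority
#' neighbour count c:
#' SAFE when c < m/2, DANGER when m/2 <= c < m, NOISE when c = m.
#' Only DANGER rows seed boundary oversampling.
#'
#' @param data Feature table the assignment was computed on.
#' @param assignment A [cluster_features()] result.
#' @param m_neighbors Neighbourhood size for the danger rule (default 10).
#' @param minority Minority cluster index; default the smallest cluster.
#' @return Integer vector of row indices (into `data`) in the danger set.
#' @export
danger_set <- function(data, assignment, m_neighbors = 10,
                       minority = minority_cluster(assignment)) {
  data <- validate_feature_table(data, features = assignment$features)
  labels <- assignment$labels
  if (!any(labels == minority)) stop_stressaug("Empty minority cluster.", "empty_cluster")
  Xs <- standardize_with(data, assignment)
  n <- nrow(Xs)
  m <- min(m_neighbors, n - 1)
  minority_idx <- which(labels == minority)
  D <- as.matrix(stats::dist(Xs))
  keep <- vapply(minority_idx, function(i) {
    nn <- order(D[i, -i])  # indices into the n-1 others
    others <- seq_len(n)[-i]
    nn_idx <- others[nn[seq_len(m)]]
    c_maj <- sum(labels[nn_idx] != minority)
    c_maj >= m / 2 && c_maj < m
  }, logical(1))
  minority_idx[keep]
}

#' Oversample the minority cluster at its boundary (SMOTE for regression)
#'
#' Generates `n_synth = max(0, ceiling(target_ratio * |majority|) -
#' |minority|)` synthetic rows. Seed rows x_d cycle round-robin through the
#' danger set; each synthetic is `x_new = x_d + u * (x_nn - x_d)` with
#' u ~ Uniform(0,1) and x_nn one of x_d's `k_neighbors` nearest minority rows
#' (standardized space). With `interpolate_target` the target shares the same
#' u, `y_new = y_d + u * (y_nn - y_d)`, keeping synthetics on the local
#' linear response; otherwise the seed's target is copied.
#'
#' When the danger set is empty but synthetics are requested, the sampler
#' falls back to classic SMOTE over all minority rows (with a message).
#'
#' With k > 2 clusters, every non-largest cluster is oversampled against the
#' largest cluster's size using the same rule.
#'
#' @param data Feature table with target.
#' @param assignment A [cluster_features()] result for `data`; computed with
#'   defaults when `NULL`.
#' @param k_neighbors Interpolation neighbour count (default 5).
#' @param m_neighbors Danger-rule neighbourhood size (default 10);
#'   must be >= `k_neighbors`.
#' @param target_ratio Desired minority/majority size ratio after
#'   oversampling, in (0, 1] (default 1).
#' @param interpolate_target Interpolate y with the feature coefficient u?
#' @param features,target Column names.
#' @param seed Integer seed.
#' @return The input table with synthetic rows appended
#'   (provenance `"smote"`).
#' @export
smote_augment <- function(data, assignment = NULL, k_neighbors = 5,
                          m_neighbors = 10, target_ratio = 1,
                          interpolate_target = TRUE,
                          features = default_features(), target = "ts",
                          seed = NULL) {
  if (k_neighbors < 1) stop_stressaug("`k_neighbors` must be >= 1.", "spec")
  if (m_neighbors < k_neighbors) {
    stop_stressaug("`m_neighbors` must be >= `k_neighbors`.", "spec")
  }
  if (target_ratio <= 0 || target_ratio > 1) {
    stop_stressaug("`target_ratio` must be in (0, 1].", "spec")
  }
  data <- validate_feature_table(data, features = features, target = target,
                                 require_target = TRUE)
  if (!"provenance" %in% names(data)) data$provenance <- rep("original", nrow(data))
  if (is.null(assignment)) {
    assignment <- cluster_features(data, k = 2, features = features, seed = seed)
  }
  majority_size <- max(assignment$sizes)
  largest <- which.max(assignment$sizes)
  Xs <- standardize_with(data, assignment)
  y <- data[[target]]

  synth_all <- list()
  with_seed(seed, {
    for (cl in seq_len(assignment$k)) {
      if (cl == largest) next
      minority_idx <- which(assignment$labels == cl)
      n_synth <- max(0L, as.integer(ceiling(target_ratio * majority_size)) -
                       length(minority_idx))
      if (n_synth == 0L) next
      if (length(minority_idx) < k_neighbors + 1) {
        stop_stressaug("Too few minority rows for the requested `k_neighbors`.",
                       "too_few_minority")
      }
      danger <- danger_set(data, assignment, m_neighbors = m_neighbors,
                           minority = cl)
      if (length(danger) == 0) {
        inform("Danger set is empty; falling back to classic SMOTE over all minority rows.")
        danger <- minority_idx
      }
      # k nearest minority rows per danger seed, in standardized space
      nn_of <- lapply(danger, function(i) {
        cand <- setdiff(minority_idx, i)
        d <- sqrt(colSums((t(Xs[cand, , drop = FALSE]) - Xs[i, ])^2))
        cand[order(d)[seq_len(min(k_neighbors, length(cand)))]]
      })
      seed_rows <- danger[((seq_len(n_synth) - 1L) %% length(danger)) + 1L]
      u <- runif(n_synth)
      nn_rows <- vapply(seq_len(n_synth), function(s) {
        pool <- nn_of[[match(seed_rows[s], danger)]]
        pool[sample.int(length(pool), 1)]
      }, integer(1))
      Xd <- as.matrix(data[seed_rows, features])
      Xn <- as.matrix(data[nn_rows, features])
      Snew <- Xd + u * (Xn - Xd)
      out <- tibble::as_tibble(as.data.frame(Snew))
      names(out) <- features
      out[[target]] <- if (interpolate_target) {
        y[seed_rows] + u * (y[nn_rows] - y[seed_rows])
      } else {
        y[seed_rows]
      }
      out$provenance <- rep("smote", n_synth)
      synth_all[[length(synth_all) + 1]] <- out
    }
  })
  if (length(synth_all) == 0) return(data)
  dplyr::bind_rows(data, synth_all)
}

#' Detect imbalance and oversample in one step
#'
#' Convenience wrapper: [cluster_features()] with `k` clusters, then
#' [smote_augment()] at the minority boundary.
#'
#' @inheritParams smote_augment
#' @param k Cluster count for imbalance detection (default 2).
#' @return The table with smote rows appended.
#' @export
balance_smote <- function(data, k = 2, k_neighbors = 5, m_neighbors = 10,
                          target_ratio = 1, interpolate_target = TRUE,
                          features = default_features(), target = "ts",
                          seed = NULL) {
  assignment <- cluster_features(data, k = k, features = features,
                                 seed = stage_seed(seed, "kmeans"))
  smote_augment(data, assignment, k_neighbors = k_neighbors,
                m_neighbors = m_neighbors, target_ratio = target_ratio,
                interpolate_target = interpolate_target, features = features,
                target = target, seed = stage_seed(seed, "smote"))
}
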