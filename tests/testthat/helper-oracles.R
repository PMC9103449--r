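# Independent oracles used by both the unit and acceptance suites.

# all permutations of 1..d, built recursively (no extra dependency)
all_permutations <- function(d) {
  if (d == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(d - 1)
  out <- NULL
  for (j in seq_len(d)) {
    rest <- setdiff(seq_len(d), j)
    out <- rbind(out, cbind(j, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Shapley values by brute-force averaging of marginal contributions over all
# d! feature orderings; independent of the coalition-enumeration code path.
permutation_shapley <- function(predict_fn, background, x, features) {
  d <- length(features)
  B <- as.matrix(background[, features])
  v <- function(s) {
    M <- B
    if (length(s) > 0) M[, s] <- matrix(as.numeric(x[features[s]]),
                                        nrow(B), length(s), byrow = TRUE)
    df <- tibble::as_tibble(as.data.frame(M))
    names(df) <- features
    mean(predict_fn(df))
  }
  perms <- all_permutations(d)
  phi <- numeric(d)
  for (p in seq_len(nrow(perms))) {
    s <- integer(0)
    for (j in perms[p, ]) {
      phi[j] <- phi[j] + (v(c(s, j)) - v(s)) / nrow(perms)
      s <- c(s, j)
    }
  }
  setNames(phi, features)
}

# Per-row linear-system check that a synthetic row is a convex combination
# x_d + u (x_nn - x_d) of two minority originals, with the target sharing u.
smote_row_explained <- function(x, y, Xmin, ymin, feature_tol = 1e-9,
                                target_tol = 1e-6) {
  for (a in seq_len(nrow(Xmin))) {
    for (b in seq_len(nrow(Xmin))) {
      if (a == b) next
      d <- Xmin[b, ] - Xmin[a, ]
      if (all(abs(d) < 1e-12)) next
      u <- sum((x - Xmin[a, ]) * d) / sum(d * d)
      if (u < -1e-9 || u > 1 + 1e-9) next
      if (sqrt(sum((x - (Xmin[a, ] + u * d))^2)) < feature_tol &&
          abs(ymin[a] + u * (ymin[b] - ymin[a]) - y) < target_tol) {
        return(TRUE)
      }
    }
  }
  FALSE
}
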