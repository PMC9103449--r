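test_that("K-means recovers separated blobs and handles degenerate k", {
  # 2D toy set: two tight pairs far apart; the 2-partition optimum is exact
  toy <- tibble::tibble(a = c(0, 0, 10, 10), b = c(0, 1, 10, 11),
                        ts = c(1, 2, 3, 4))
  cl <- cluster_features(toy, k = 2, features = c("a", "b"), seed = 1)
  expect_setequal(cl$sizes, c(2, 2))
  expect_equal(cl$labels[1], cl$labels[2])
  expect_equal(cl$labels[3], cl$labels[4])
  expect_false(cl$labels[1] == cl$labels[3])
  # centroids sit at the pair means in standardized space
  Xs <- stressaug:::standardize_with(toy, cl)
  for (g in 1:2) {
    expect_equal(unname(cl$centroids[g, ]),
                 unname(colMeans(Xs[cl$labels == g, , drop = FALSE])),
                 tolerance = 1e-8)
  }

  one <- cluster_features(toy, k = 1, features = c("a", "b"))
  expect_true(all(one$labels == 1L))
  expect_equal(unname(one$centroids[1, ]), c(0, 0), tolerance = 1e-12)

  expect_error(cluster_features(toy[1:2, ], k = 3, features = c("a", "b")),
               class = "stressaug_error_too_few_rows")
})

test_that("danger rule classifies SAFE, DANGER and NOISE by hand-checkable neighborhoods", {
  # 1D: minority {0, 4}, majority {5, 6, 7, 8}, m = 4. Enumerating by hand:
  # x=0: nearest four are {4,5,6,7} -> c = 3 majority, 2 <= 3 < 4 -> DANGER
  # x=4: nearest are {5,6,7} then a tie at distance 4 between 0 and 8,
  #      resolved to the lower row index (0, minority) -> c = 3 -> DANGER
  dat <- tibble::tibble(x = c(0, 4, 5, 6, 7, 8), ts = 1:6)
  assignment <- structure(list(
    k = 2, labels = c(1L, 1L, 2L, 2L, 2L, 2L),
    centroids = NULL, sizes = c(2L, 4L),
    center = c(x = mean(dat$x)), scale = c(x = sd(dat$x)), features = "x"
  ), class = "cluster_assignment")
  expect_equal(danger_set(dat, assignment, m_neighbors = 4), c(1L, 2L))

  # push the lone point far out: each minority point's m neighbors are all
  # majority -> NOISE, excluded (for x = 4 the far point 20 leaves the
  # neighborhood, so its 4 nearest are 5..8)
  far <- tibble::tibble(x = c(20, 4, 5, 6, 7, 8), ts = 1:6)
  expect_length(danger_set(far, assignment, m_neighbors = 4), 0)

  # fully separated clusters: every minority neighborhood is minority -> SAFE
  sep <- tibble::tibble(x = c(0, 0.1, 0.2, 100, 101, 102, 103, 104), ts = 1:8)
  asg2 <- cluster_features(sep, k = 2, features = "x", seed = 1)
  expect_length(danger_set(sep, asg2, m_neighbors = 3), 0)
})

test_that("smote rows are convex combinations of minority parents, target sharing u", {
  # two danger minority points on a segment; one synthetic must sit between
  dat <- tibble::tibble(
    omega = c(0, 1, 10, 10.5, 11, 11.5, 12, 12.5),
    eps_h = c(0, 1, 10, 10.5, 11, 11.5, 12, 12.5),
    eps_nh = c(0, 1, 10, 10.5, 11, 11.5, 12, 12.5),
    ts = c(0, 1, 10, 10.5, 11, 11.5, 12, 12.5),
    provenance = "original"
  )
  asg <- cluster_features(dat, k = 2, seed = 1)
  out <- smote_augment(dat, asg, k_neighbors = 1, m_neighbors = 2,
                       target_ratio = 0.5, seed = 4)
  synth <- out[out$provenance == "smote", ]
  expect_gt(nrow(synth), 0)
  # features and target share the interpolation coefficient u
  for (i in seq_len(nrow(synth))) {
    u <- (synth$omega[i] - 0) / (1 - 0)
    if (synth$omega[i] > 1.5) { # parents are the second pair ordering
      next
    }
    expect_equal(synth$eps_h[i], u, tolerance = 1e-9)
    expect_equal(synth$ts[i], u, tolerance = 1e-9)
    expect_true(u >= 0 && u <= 1)
  }
})

test_that("per-row linear-system oracle: every smote row solves x_new = x_d + u (x_nn - x_d)", {
  dat <- benchmark_table()
  aug <- augment_nni(dat, seed = 21)
  bal <- balance_smote(aug, seed = 22)
  synth <- bal[bal$provenance == "smote", ]
  expect_gt(nrow(synth), 0)
  minority <- {
    asg <- cluster_features(aug, k = 2, seed = stressaug:::stage_seed(22, "kmeans"))
    which(asg$labels == which.min(asg$sizes))
  }
  Xmin <- as.matrix(aug[minority, default_features()])
  ymin <- aug$ts[minority]
  ok <- vapply(seq_len(nrow(synth)), function(i) {
    smote_row_explained(as.numeric(synth[i, default_features()]), synth$ts[i],
                        Xmin, ymin)
  }, logical(1))
  expect_true(all(ok))
  # interpolated targets lie between their parents' (convexity)
  expect_true(all(synth$ts >= min(ymin) - 1e-9 & synth$ts <= max(ymin) + 1e-9))
})

test_that("oversampling bounds and no-op hold", {
  dat <- benchmark_table()
  aug <- augment_nni(dat, seed = 21)
  asg <- cluster_features(aug, k = 2, seed = 7)
  out <- smote_augment(aug, asg, seed = 7)
  n_min <- min(asg$sizes)
  n_maj <- max(asg$sizes)
  added <- nrow(out) - nrow(aug)
  expect_equal(added, max(0, ceiling(1 * n_maj) - n_min))

  # already balanced at the requested ratio -> identity
  ratio <- n_min / n_maj
  noop <- smote_augment(aug, asg, target_ratio = ratio, seed = 7)
  expect_identical(noop, aug)

  expect_error(smote_augment(aug, asg, target_ratio = 0),
               class = "stressaug_error_spec")
  expect_error(smote_augment(aug, asg, k_neighbors = 5, m_neighbors = 2),
               class = "stressaug_error_spec")
})
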