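test_that("boosted surrogate handles degenerate targets and is deterministic", {
  dat <- toy_table(n = 20)
  flat <- dplyr::mutate(dat, ts = 7.5)
  m <- fit_surrogate(flat, seed = 1)
  expect_equal(predict(m, flat), rep(7.5, 20), tolerance = 1e-6)

  m1 <- fit_surrogate(dat, seed = 3)
  m2 <- fit_surrogate(dat, seed = 3)
  expect_identical(predict(m1, dat), predict(m2, dat))

  # prediction is invariant to training-row order
  shuffled <- dat[rev(seq_len(nrow(dat))), ]
  m3 <- fit_surrogate(shuffled, seed = 3)
  expect_equal(predict(m3, dat), predict(m1, dat), tolerance = 1e-10)

  expect_error(fit_surrogate(dplyr::select(dat, -ts)),
               class = "stressaug_error_missing_target")
})

test_that("training fit on the augmented benchmark reaches the expected regime", {
  dat <- benchmark_table()
  bal <- balance_smote(augment_nni(dat, seed = 1), seed = 2)
  m <- fit_surrogate(bal, seed = 3)
  expect_gte(r2_score(bal$ts, predict(m, bal)), 0.9)
})

test_that("a 1-tree depth-1 unit-rate booster reduces to the best regression stump", {
  dat <- toy_table(n = 30, seed = 9)
  spec <- surrogate_spec(n_trees = 1, max_depth = 1, eta = 1, reg_lambda = 0)
  m <- fit_surrogate(dat, spec, seed = 1)
  got <- predict(m, dat)

  # brute-force best single split on any feature by SSE reduction
  y <- dat$ts
  base <- mean(y)
  best <- list(sse = sum((y - base)^2), pred = rep(base, length(y)))
  for (f in default_features()) {
    x <- dat[[f]]
    for (cut in sort(unique(x))[-1]) {
      left <- x < cut
      pred <- ifelse(left, mean(y[left]), mean(y[!left]))
      sse <- sum((y - pred)^2)
      if (sse < best$sse - 1e-12) best <- list(sse = sse, pred = pred)
    }
  }
  expect_equal(got, best$pred, tolerance = 1e-5)
})

test_that("baselines: exact OLS recovery, constant targets, svr sanity", {
  dat <- toy_table(n = 40, seed = 2)
  dat$ts <- 3 + 0.5 * dat$omega + 2 * dat$eps_h - 1 * dat$eps_nh
  mlr <- fit_baseline(dat, "mlr")
  expect_equal(unname(mlr$fit$coef), c(3, 0.5, 2, -1), tolerance = 1e-9)
  expect_equal(predict(mlr, dat), dat$ts, tolerance = 1e-9)

  flat <- dplyr::mutate(toy_table(n = 20), ts = 4.2)
  expect_equal(predict(fit_baseline(flat, "mlr"), flat), rep(4.2, 20),
               tolerance = 1e-9)
  expect_equal(predict(fit_baseline(flat, "svr"), flat), rep(4.2, 20),
               tolerance = 0.15) # epsilon-insensitive tube allows slack

  # duplicated column makes the design singular; minimum-norm fit still predicts
  dup <- dat
  dup$omega2 <- dup$omega
  expect_message(
    msingular <- fit_baseline(dup, "mlr",
                              features = c("omega", "omega2", "eps_h", "eps_nh")),
    "minimum-norm"
  )
  expect_equal(predict(msingular, dup), dat$ts, tolerance = 1e-6)
})

test_that("cv_score partitions correctly and is invariant to feature order", {
  dat <- toy_table(n = 40, seed = 4)
  dat$ts <- 1 + 2 * dat$omega - 3 * dat$eps_h + 0.5 * dat$eps_nh
  expect_equal(cv_score(dat, "mlr", folds = 10, seed = 1), 1, tolerance = 1e-9)

  expect_error(cv_score(dat[1:5, ], folds = 10), class = "stressaug_error_too_few_rows")
  expect_error(cv_score(dat, folds = nrow(dat)), class = "stressaug_error_singleton_fold")

  reordered <- dat[, c("eps_nh", "omega", "eps_h", "ts", "provenance")]
  s1 <- cv_score(dat, surrogate_spec(n_trees = 10), folds = 5, seed = 6)
  s2 <- cv_score(reordered, surrogate_spec(n_trees = 10), folds = 5, seed = 6)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("permuted targets destroy cross-validated skill", {
  dat <- benchmark_table()
  scores <- vapply(1:5, function(s) {
    shuffled <- dat
    shuffled$ts <- withr::with_seed(s, sample(dat$ts))
    cv_score(shuffled, surrogate_spec(), folds = 10, seed = s)
  }, numeric(1))
  expect_lte(mean(scores), 0.1)
})

test_that("coordinate-wise tuning sweeps grids in order with greedy argmax", {
  dat <- benchmark_table()
  aug <- augment_nni(dat, points_per_sample = 5, seed = 1)

  single <- tune_surrogate(aug, grids = list(n_trees = 55, eta = 0.16,
                                             max_depth = 8, reg_lambda = 120),
                           folds = 5, seed = 2)
  expect_equal(unclass(single$spec), unclass(surrogate_spec()))
  expect_equal(nrow(single$trace), 4) # one row per grid point

  grids <- list(n_trees = c(20, 55), eta = c(0.16, 0.3), reg_lambda = c(60, 120))
  tuned <- tune_surrogate(aug, grids = grids, folds = 5, seed = 2)
  expect_equal(nrow(tuned$trace), sum(lengths(grids)))
  # greedy over a grid containing the default cannot do worse than the default
  default_score <- cv_score(aug, surrogate_spec(), folds = 5, seed = 2)
  tuned_score <- cv_score(aug, tuned$spec, folds = 5, seed = 2)
  expect_gte(tuned_score, default_score - 1e-12)

  expect_error(tune_surrogate(aug, grids = list()), class = "stressaug_error_spec")
  expect_error(surrogate_spec(eta = 0), class = "stressaug_error_spec")
})
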