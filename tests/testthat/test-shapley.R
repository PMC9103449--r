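test_that("constant and additive models have closed-form attributions", {
  bg <- toy_table(n = 15, seed = 1)
  const_fn <- function(df) rep(5, nrow(df))
  sh <- exact_shapley(const_fn, bg[1:4, ], background = bg)
  expect_true(all(abs(as.matrix(sh$phi)) < 1e-12))
  expect_equal(sh$base_value, 5)

  g1 <- function(x) 2 * x
  g2 <- function(x) x^2
  g3 <- function(x) sin(x)
  add_fn <- function(df) g1(df$omega) + g2(df$eps_h) + g3(df$eps_nh)
  sh <- exact_shapley(add_fn, bg[1:5, ], background = bg)
  # additivity: phi_j = g_j(x_j) - mean_background g_j
  expect_equal(sh$phi$omega, g1(bg$omega[1:5]) - mean(g1(bg$omega)), tolerance = 1e-10)
  expect_equal(sh$phi$eps_h, g2(bg$eps_h[1:5]) - mean(g2(bg$eps_h)), tolerance = 1e-10)
  expect_equal(sh$phi$eps_nh, g3(bg$eps_nh[1:5]) - mean(g3(bg$eps_nh)), tolerance = 1e-10)
})

test_that("coalition enumeration equals the d! permutation brute force on benchmark rows", {
  dat <- benchmark_table()
  model <- fit_surrogate(balance_smote(augment_nni(dat, seed = 1), seed = 2),
                         seed = 3)
  rows <- dat[1:10, ]
  sh <- exact_shapley(model, rows, background = rows)
  predict_fn <- function(df) predict(model, df)
  for (i in 1:10) {
    oracle <- permutation_shapley(predict_fn, rows, rows[i, ], model$features)
    expect_lt(max(abs(as.numeric(sh$phi[i, ]) - as.numeric(oracle))), 1e-10)
  }
  # local accuracy on every explained row
  recon <- sh$base_value + rowSums(as.matrix(sh$phi))
  expect_equal(recon, predict(model, rows), tolerance = 1e-8)
})

test_that("symmetry and dummy axioms hold on toy models", {
  bg <- tibble::tibble(omega = c(0, 1, 2, 3), eps_h = c(3, 2, 1, 0),
                       eps_nh = c(1, 1, 1, 1), ts = 1:4)
  # symmetric model on a symmetric input: both features used identically
  sym_fn <- function(df) df$omega + df$eps_h
  x <- tibble::tibble(omega = 2, eps_h = 2, eps_nh = 1)
  sh <- exact_shapley(sym_fn, x, background = bg)
  expect_equal(sh$phi$omega, sh$phi$eps_h, tolerance = 1e-12)

  # a feature the model never uses gets zero attribution everywhere
  dummy_fn <- function(df) 3 * df$omega
  sh2 <- exact_shapley(dummy_fn, bg, background = bg)
  expect_true(all(sh2$phi$eps_nh == 0))
  expect_true(all(sh2$phi$eps_h == 0))

  expect_error(
    exact_shapley(dummy_fn, bg, background = bg,
                  features = paste0("f", 1:13)),
    class = "stressaug_error_too_many_features"
  )
})

test_that("importance ranking is invariant to duplicated rows and ranks used features first", {
  dat <- toy_table(n = 12, seed = 3)
  only_first <- function(df) 4 * df$omega
  imp <- exact_shapley(only_first, dat)$importance
  expect_equal(imp$feature[1], "omega")
  expect_equal(imp$mean_abs_shap[2:3], c(0, 0))

  model <- fit_surrogate(balance_smote(augment_nni(benchmark_table(), seed = 1),
                                       seed = 2), seed = 3)
  base <- importance_ranking(model, benchmark_table())
  doubled <- dplyr::bind_rows(benchmark_table(), benchmark_table())
  dup <- importance_ranking(model, doubled)
  expect_equal(base$feature, dup$feature)
  expect_equal(base$mean_abs_shap, dup$mean_abs_shap, tolerance = 1e-10)
})

test_that("surface grids index correctly and agree with direct prediction", {
  dat <- benchmark_table()
  model <- fit_surrogate(augment_nni(dat, seed = 1), seed = 2)

  g <- predict_surface(model, eps_h = c(1, 3), omega = c(5, 15),
                       eps_nh_fixed = 0.38)
  expect_equal(dim(g$ts), c(2, 2))
  direct <- predict(model, tibble::tibble(
    omega = c(5, 15, 5, 15), eps_h = c(1, 1, 3, 3), eps_nh = 0.38))
  expect_equal(g$ts[1, 1], direct[1])
  expect_equal(g$ts[1, 2], direct[2])
  expect_equal(g$ts[2, 1], direct[3])
  expect_equal(g$ts[2, 2], direct[4])

  long <- tidy(g)
  expect_equal(nrow(long), 4)
  expect_equal(long$ts[long$eps_h == 3 & long$omega == 5], g$ts[2, 1])

  expect_error(predict_surface(model, eps_h = c(3, 1), omega = c(5, 15)),
               class = "stressaug_error_axes")
  expect_warning(predict_surface(model, eps_h = c(1, 10), omega = c(5, 15)),
                 "envelope")

  # upward trend along eps_h planted in the generator carries to the surface
  g2 <- predict_surface(model, n_grid = 40)
  top <- g2$ts[g2$eps_h >= quantile(g2$eps_h, 0.9), ]
  bottom <- g2$ts[g2$eps_h <= quantile(g2$eps_h, 0.1), ]
  expect_gt(mean(top), mean(bottom))
})
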