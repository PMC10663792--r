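test_that("hyperparameter grids enumerate the stated sets", {
  for (dh in c(100, 20, 10)) {
    g <- brt_grid(dh)
    expect_equal(nrow(g), 9L)
    expect_setequal(unique(g$learning_rate), c(0.05, 0.01, 0.005))
    expect_setequal(unique(g$bag_fraction), c(0.3, 0.5, 0.66))
  }
  expect_equal(unique(brt_grid(20)$tree_complexity), 3)
  expect_equal(unique(brt_grid(10)$tree_complexity), 5)
  g2 <- brt_grid(2)
  expect_equal(nrow(g2), 18L)
  expect_setequal(unique(g2$tree_complexity), c(5, 7))
  expect_error(brt_grid(7), "tree-complexity")
})

test_that("train/validation split follows the capped 50% rule", {
  s <- split_train_validation(8000, seed = 1)
  expect_length(s$train, 4000)
  expect_length(s$validation, 4000)
  expect_length(intersect(s$train, s$validation), 0)

  big <- split_train_validation(800000, seed = 1)
  expect_length(big$train, 15900)
  expect_length(big$validation, 784100)

  expect_identical(split_train_validation(1000, seed = 9),
                   split_train_validation(1000, seed = 9))
  expect_error(split_train_validation(1), "2 rows")
})

test_that("prediction evaluation matches closed-form Pearson and RMSE", {
  ref <- c(1, 2, 3, 4)
  perfect <- evaluate_predictions(ref, ref)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2_ss, 1)

  off <- evaluate_predictions(ref + 2, ref)
  expect_equal(off$r2, 1, tolerance = 1e-12)
  expect_equal(off$rmse, 2, tolerance = 1e-12)

  ## 4-point scalar oracle
  pred <- c(1, 1, 2, 3)
  ev <- evaluate_predictions(pred, ref)
  expect_equal(ev$r2, cor(pred, ref)^2, tolerance = 1e-12)
  expect_equal(ev$rmse, sqrt(mean((pred - ref)^2)), tolerance = 1e-12)
  expect_equal(evaluate_predictions(rep(1, 4), ref)$r2, 0)
  expect_error(evaluate_predictions(1:3, 1:4), "length")
})

test_that("constant targets yield a constant predictor with warning", {
  x <- matrix(runif(40), 20)
  expect_warning(f <- fit_brt(x, rep(3, 20), 0.05, 0.5, 3,
                              cv_folds = 3), "constant")
  expect_equal(predict(f, x), rep(3, 20))
})

test_that("a noiseless layered sum is recovered almost perfectly", {
  fx <- make_regression_fixture(2000, n_features = 5,
                                fun = "layered_sum", seed = 31)
  sp <- split_train_validation(2000, seed = 31)
  fit <- fit_brt(fx$features[sp$train, ], fx$target[sp$train],
                 learning_rate = 0.05, bag_fraction = 0.5,
                 tree_complexity = 5, cv_folds = 5, seed = 1)
  ev <- evaluate_predictions(predict(fit, fx$features[sp$validation, ]),
                             fx$target[sp$validation])
  expect_gte(ev$r2, 0.99)
})

test_that("validation accuracy reaches the analytic noise ceiling", {
  ## signal = sum of two uniform layers, sd = sqrt(2/12); Laplace scale
  ## at half the signal sd gives a ceiling around 0.67
  fx <- make_regression_fixture(6000, n_features = 5,
                                fun = "layered_sum", noise = "laplace",
                                noise_scale = 0.5 * sqrt(2 / 12),
                                seed = 41)
  sp <- split_train_validation(6000, seed = 41)
  fit <- fit_brt(fx$features[sp$train, ], fx$target[sp$train],
                 learning_rate = 0.05, bag_fraction = 0.5,
                 tree_complexity = 5, cv_folds = 5, seed = 2)
  ev <- evaluate_predictions(predict(fit, fx$features[sp$validation, ]),
                             fx$target[sp$validation])
  expect_lt(abs(ev$r2 - fx$r2_ceiling), 0.05)
})

test_that("grid search is reproducible and prefers lower cv loss", {
  fx <- make_regression_fixture(800, fun = "linear", noise = "gaussian",
                                noise_scale = 0.5, seed = 13)
  grid <- data.table::data.table(learning_rate = c(0.05, 0.05),
                                 bag_fraction = c(0.5, 0.66),
                                 tree_complexity = 3)
  f1 <- fit_best_brt(fx$features, fx$target, grid, cv_folds = 3,
                     seed = 5)
  f2 <- fit_best_brt(fx$features, fx$target, grid, cv_folds = 3,
                     seed = 5)
  expect_identical(f1$config, f2$config)
  expect_identical(f1$grid_results$cv_loss, f2$grid_results$cv_loss)
  expect_equal(f1$cv_loss, min(f1$grid_results$cv_loss))
})

test_that("more vertical detail never hurts much (monotone information)", {
  ## features: fine layers; coarse model sees their sums
  set.seed(55)
  sim <- tiny_sim()
  tab2 <- stand_year_table(sim, 20, 2)
  tab100 <- stand_year_table(sim, 20, 100)
  y <- tab2$npp
  fit_one <- function(tab) {
    x <- as.matrix(tab[, grep("^b[0-9]+$", names(tab)), with = FALSE])
    sp <- split_train_validation(nrow(tab), seed = 5)
    f <- fit_brt(x[sp$train, , drop = FALSE], y[sp$train], 0.05, 0.66,
                 3, cv_folds = 3, seed = 5, nrounds_max = 150)
    evaluate_predictions(predict(f, x[sp$validation, , drop = FALSE]),
                         y[sp$validation])$r2
  }
  expect_gte(fit_one(tab2), fit_one(tab100) - 0.03)
})
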