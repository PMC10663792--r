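test_that("stand generator is reproducible and respects bounds", {
  a <- make_stand(50, seed = 3)
  b <- make_stand(50, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(make_stand(0)), 0L)
  ln <- make_stand(2000, height_dist = "lognormal", seed = 5)
  expect_true(all(ln$height > 0 & ln$height <= 100))
})

test_that("generated moments match the requested distributions", {
  n <- 1e5
  u <- make_stand(n, hmin = 2, hmax = 50, seed = 8)
  se_mean <- (50 - 2) / sqrt(12) / sqrt(n)
  expect_lt(abs(mean(u$height) - 26), 3 * se_mean)
  expect_lt(abs(sd(u$height) - (50 - 2) / sqrt(12)),
            3 * sd(u$height) / sqrt(2 * n))
})

test_that("uniform heights force the 20:20:16 layer ratio", {
  st <- make_stand(25, hmin = 56, hmax = 56, seed = 1)
  prof <- stand_profile(st, profile_spec(20, 20))
  expect_equal(prof$layers[1] / prof$layers[3], 20 / 16,
               tolerance = 1e-9)
  expect_equal(prof$layers[1], prof$layers[2], tolerance = 1e-9)
})

test_that("laplace noise has variance 2 b^2 (Monte-Carlo oracle)", {
  set.seed(77)
  b <- 0.3
  draws <- rlaplace(1e6, b)
  expect_lt(abs(var(draws) / (2 * b^2) - 1), 0.02)
  expect_lt(abs(mean(draws)), 0.01)
  expect_error(rlaplace(10, -1), "scale")
})

test_that("regression fixtures report a correct analytic ceiling", {
  f0 <- make_regression_fixture(500, noise = "none", seed = 2)
  expect_equal(f0$r2_ceiling, 1)
  expect_identical(f0$target, f0$f)

  fg <- make_regression_fixture(5000, noise = "gaussian",
                                noise_scale = 0.5, seed = 2)
  expect_equal(fg$r2_ceiling, var(fg$f) / (var(fg$f) + 0.25),
               tolerance = 1e-12)

  fl <- make_regression_fixture(5000, noise = "laplace",
                                noise_scale = 0.5, seed = 2)
  expect_equal(fl$noise_var, 2 * 0.5^2)
  ## realized noise variance agrees with the analytic value
  expect_lt(abs(var(fl$target - fl$f) / fl$noise_var - 1), 0.1)

  ## ceiling decreases monotonically with the noise scale
  ceilings <- sapply(c(0, 0.2, 0.5, 1), function(b)
    make_regression_fixture(1000, noise = "laplace", noise_scale = b,
                            seed = 4)$r2_ceiling)
  expect_true(all(diff(ceilings) < 0))
  expect_true(all(ceilings >= 0 & ceilings <= 1))
})
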