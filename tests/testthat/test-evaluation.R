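test_that("metrics match hand computation and their identities", {
  # y = (0,0,4,4), yhat = (1,-1,3,5): residuals (1,-1,-1,1)
  m <- compute_metrics(c(0, 0, 4, 4), c(1, -1, 3, 5))
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, 1 - 4 / 16)       # SST about the mean 2 is 16
  expect_equal(m$sd, 2)                # population SD
  expect_equal(m$rpd, 2)
  expect_equal(m$rpd * m$rmse, m$sd, tolerance = 1e-12)

  # perfect predictions: R2 = 1, RMSE = 0, RPD flagged infinite
  y <- c(4.5, 5.0, 5.5, 6.0)
  mp <- compute_metrics(y, y)
  expect_equal(mp$r2, 1)
  expect_equal(mp$rmse, 0)
  expect_true(is.infinite(mp$rpd) && mp$rpd_infinite)

  # predicting the mean gives R2 = 0
  expect_equal(compute_metrics(y, rep(mean(y), 4))$r2, 0)

  expect_error(compute_metrics(rep(1, 4), c(1, 2, 1, 2)), "zero-variance")
  expect_error(compute_metrics(1, 1), "n >= 2")
})

test_that("RPD times RMSE returns the SD exactly on random data", {
  withr::with_seed(23, {
    for (i in 1:10) {
      y <- rnorm(30); yh <- y + rnorm(30, 0, 0.5)
      m <- compute_metrics(y, yh)
      expect_equal(m$rpd * m$rmse, m$sd, tolerance = 1e-12)
      expect_lte(m$r2, 1)
    }
  })
})

test_that("the typeset R2 variant is available for audit", {
  y <- c(0, 0, 4, 4); yh <- c(1, -1, 3, 5)
  m <- compute_metrics(y, yh, r2_method = "predicted-mean")
  expect_equal(m$r2, 1 - 4 / sum((yh - 2)^2))
})

test_that("fold assignment partitions every sample exactly once", {
  for (seed in 1:5) {
    f <- make_folds(23, 5, seed)
    expect_length(f, 23)
    expect_setequal(unique(f), 1:5)
    expect_lte(diff(range(table(f))), 1)   # near-equal fold sizes
    expect_identical(f, make_folds(23, 5, seed))
  }
  expect_error(make_folds(3, 5, 1), "n >= K")
})

test_that("repeated K-fold is bit-reproducible and covers each sample per rep", {
  inst <- make_instance(40, 6, noise = 0.3, seed = 33)
  r1 <- run_repeated_kfold(inst$X, inst$y, plsr_recipe(ncomp = 4),
                           K = 5, reps = 4, base_seed = 11)
  r2 <- run_repeated_kfold(inst$X, inst$y, plsr_recipe(ncomp = 4),
                           K = 5, reps = 4, base_seed = 11)
  expect_identical(r1$cells, r2$cells)
  expect_identical(r1$folds, r2$folds)
  for (rep in 1:4) {
    expect_setequal(r1$folds[, rep], 1:5)
    expect_true(all(table(r1$folds[, rep]) == 8))
    # fold assignment re-derivable from the recorded per-rep seed
    expect_identical(r1$folds[, rep], make_folds(40, 5, r1$seeds[rep]))
  }
})

test_that("leave-one-out limit runs and noise-free data give R2 ~ 1", {
  inst <- make_instance(10, 3, noise = 0.2, seed = 44)
  loo <- run_repeated_kfold(inst$X, inst$y, plsr_recipe(ncomp = 2),
                            K = 10, reps = 1, base_seed = 2)
  expect_equal(nrow(loo$cells), 10)
  expect_true(all(is.na(loo$cells$r2)))    # single-sample folds: R2 undefined
  expect_true(all(loo$cells$rmse >= 0))

  exact <- make_instance(30, 5, noise = 0, seed = 45)
  rep <- run_repeated_kfold(exact$X, exact$y, plsr_recipe(ncomp = 5),
                            K = 5, reps = 2, base_seed = 3)
  expect_gte(rep$aggregate$mean["r2"], 0.99)
})

test_that("selection inside the recipe is refit on every training fold", {
  withr::with_seed(55, {
    X <- matrix(rnorm(50 * 20), 50, 20)
    y <- 3 * X[, 4] + rnorm(50, 0, 0.2)
  })
  recipe <- plsr_recipe(ncomp = 2, selector = function(X, y, seed) {
    select_by_beta(fit_plsr(X, y, ncomp = 2), n_keep = 3)
  }, label = "beta")
  rep <- run_repeated_kfold(X, y, recipe, K = 5, reps = 2, base_seed = 7)
  expect_true(all(rep$cells$n_variables == 3))
  expect_gte(rep$aggregate$mean["r2"], 0.9)
})

test_that("KS statistic matches its closed forms and the brute-force oracle", {
  # n = 1 at the fitted-normal median: D+ = D- = 0.5
  k1 <- ks_statistic(3.7)
  expect_equal(c(k1$D, k1$D_plus, k1$D_minus), c(0.5, 0.5, 0.5))

  # exact normal quantiles at (i - 0.5)/n against the true parameters
  k20 <- ks_statistic(qnorm((1:20 - 0.5) / 20), mean = 0, sd = 1)
  expect_equal(k20$D, 0.025, tolerance = 1e-12)

  withr::with_seed(66, {
    for (i in 1:20) {
      x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2),
                 sd = runif(1, 0.5, 3))
      k <- ks_statistic(x)
      expect_equal(k$D, ks_oracle(x, k$mean, k$sd), tolerance = 1e-9)
      expect_equal(k$D, max(k$D_plus, k$D_minus))
      expect_true(k$D >= 0 && k$D <= 1)
    }
  })
})

test_that("KS statistic is affine invariant with fitted parameters", {
  withr::with_seed(67, {
    x <- rexp(30)
    d0 <- ks_statistic(x)$D
    expect_equal(ks_statistic(2.5 * x + 7)$D, d0, tolerance = 1e-10)
    expect_equal(ks_statistic(0.1 * x - 3)$D, d0, tolerance = 1e-10)
  })
  expect_error(ks_statistic(rep(2, 5)), "zero sample")
})

test_that("model comparison tables line up and guard their protocol", {
  inst <- make_instance(30, 8, noise = 0.3, seed = 70)
  full <- run_repeated_kfold(inst$X, inst$y, plsr_recipe(ncomp = 4),
                             K = 5, reps = 2, base_seed = 9)
  same <- run_repeated_kfold(inst$X, inst$y, plsr_recipe(ncomp = 4),
                             K = 5, reps = 2, base_seed = 9)
  tab <- compare_models(full, list(dup = same))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$r2[1], tab$r2[2])       # identical recipes, identical rows
  expect_equal(tab$rmse[1], tab$rmse[2])

  # empty optimized map: full row only
  expect_equal(nrow(compare_models(full)), 1)

  other <- run_repeated_kfold(inst$X, inst$y, plsr_recipe(ncomp = 4),
                              K = 5, reps = 2, base_seed = 10)
  expect_error(compare_models(full, list(bad = other)), "matching fold seeds")
})
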