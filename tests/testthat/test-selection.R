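test_that("beta selection keeps the largest coefficients, ties to lower index", {
  # a dominant single coefficient is found
  withr::with_seed(14, {
    X <- qr.Q(qr(matrix(rnorm(120), 20, 6)))
    y <- 5 * X[, 3] + rnorm(20, 0, 0.01)
    m <- fit_plsr(X, y, ncomp = 2)
    sel <- select_by_beta(m, n_keep = 1)
    expect_identical(sel$indices, 3L)
    expect_equal(sel$scores, abs(m$coefficients))

    # duplicated predictor makes |beta| exactly tied; lower index wins
    Xd <- cbind(X[, 3], X[, 3])
    md <- fit_plsr(Xd, y, ncomp = 1)
    expect_equal(abs(md$coefficients[1]), abs(md$coefficients[2]))
    expect_identical(select_by_beta(md, n_keep = 1)$indices, 1L)
  })
})

test_that("beta selection honors its count bounds and identity limit", {
  inst <- make_instance(15, 8, seed = 6)
  m <- fit_plsr(inst$X, inst$y, ncomp = 3)
  expect_identical(select_by_beta(m, n_keep = 8)$indices, 1:8)
  expect_error(select_by_beta(m, n_keep = 0), "n_keep")
  expect_error(select_by_beta(m, n_keep = 9), "n_keep")
})

test_that("VIP selection uses a strict threshold and flags empty selections", {
  vip <- structure(list(vip = c(1.2, 0.8, 1.0), threshold = 1),
                   class = "vip_result")
  expect_identical(select_by_vip(vip)$indices, 1L)   # strict: 1.0 excluded
  vip1 <- structure(list(vip = 1, threshold = 1), class = "vip_result")
  expect_error(select_by_vip(vip1), class = "cafspec_empty_selection")
  # pigeonhole: sum v^2 = p forces some v_j >= 1 unless all are exactly 1
  for (s in 1:10) {
    inst <- make_instance(20, 7, noise = 1, seed = 200 + s)
    v <- compute_vip(fit_plsr(inst$X, inst$y, 3))$vip
    expect_true(any(v >= 1) || all(abs(v - 1) < 1e-12))
  }
})

test_that("CAFS scores identify planted single-band signals", {
  # p = 60 split into 10 bands of 6; only bands 3 and 9 carry signal,
  # confined within one band each so leave-band-out scoring is sharp.
  # Strength 3 keeps the include/exclude design balanced enough for the
  # main-effects score to be reliable at this array size.
  n_hits <- 0
  for (rep in 1:20) {
    withr::with_seed(300 + rep, {
      X <- matrix(rnorm(80 * 60), 80, 60)
      y <- rowSums(X[, 13:18]) + rowSums(X[, 49:54]) + rnorm(80, 0, 0.3)
    })
    sel <- cafs_select(X, y, t = 3, n_bands = 10, n_final = 12,
                       ncomp = 5, cv_folds = 3, seed = rep)
    top2 <- order(-sel$params$band_score)[1:2]
    if (setequal(top2, c(3, 9))) n_hits <- n_hits + 1
  }
  expect_gte(n_hits, 18)   # allow rare CV-noise inversions
})

test_that("CAFS is deterministic under a fixed seed", {
  withr::with_seed(77, {
    X <- matrix(rnorm(60 * 40), 60, 40)
    y <- rowSums(X[, 11:14]) + rnorm(60, 0.2)
  })
  s1 <- cafs_select(X, y, n_bands = 8, n_final = 6, ncomp = 4, seed = 5)
  s2 <- cafs_select(X, y, n_bands = 8, n_final = 6, ncomp = 4, seed = 5)
  expect_identical(s1$indices, s2$indices)
  expect_identical(s1$params$row_rmse, s2$params$row_rmse)
  expect_identical(s1$seed, 5)
})

test_that("pure-noise responses produce no score beyond the permutation null", {
  withr::with_seed(88, {
    X <- matrix(rnorm(60 * 40), 60, 40)
    y <- rnorm(60)
    perm_max <- vapply(1:19, function(i) {
      yp <- sample(y)
      sp <- cafs_select(X, yp, n_bands = 8, n_final = 6, ncomp = 3,
                        seed = 1000 + i)
      max(sp$params$band_score, na.rm = TRUE)
    }, numeric(1))
  })
  obs <- cafs_select(X, y, n_bands = 8, n_final = 6, ncomp = 3, seed = 999)
  expect_lte(max(obs$params$band_score, na.rm = TRUE),
             stats::quantile(perm_max, 0.95) + 1e-12)
})

test_that("selection_result enforces its invariants", {
  expect_error(selection_result("beta", integer(0), rep(1, 5)),
               class = "cafspec_empty_selection")
  expect_error(selection_result("beta", 6L, rep(1, 5)), "outside")
  expect_error(selection_result("beta", 2L, c(1, NA, 1, 1, 1)),
               "non-finite")
  sel <- selection_result("beta", c(3L, 1L, 3L), c(5, 2, 9))
  expect_identical(sel$indices, c(1L, 3L))   # sorted, unique
})

test_that("selection results export as index/wavelength/score tables", {
  inst <- make_instance(15, 6, seed = 17)
  sel <- select_by_beta(fit_plsr(inst$X, inst$y, 2), n_keep = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_selection(sel, path, wavelengths = seq(1100, 1110, by = 2))
  tab <- read.csv(path)
  expect_named(tab, c("index", "wavelength_nm", "score"))
  expect_equal(nrow(tab), 3)
})
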