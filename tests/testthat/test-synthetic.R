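noiseless <- function(...) {
  fermentation_scenario(ph_jitter = 0, tss_jitter = 0, ph_noise = 0,
                        tss_noise = 0, drift_sd = 0, noise_sd = 0, ...)
}

test_that("default scenario emits the full 3x7x2x50 = 2100 design", {
  b <- make_benchmark(fermentation_scenario())
  expect_equal(nrow(b$spectra$values), 2100)
  expect_equal(length(b$ph$y), 2100)
  expect_length(b$spectra$wavelengths, 501)
  expect_identical(b$spectra$mode, "reflectance")
  # shrunken scenario for fast tests: 1 x 3 x 1 x 5 = 15 rows
  expect_equal(nrow(make_benchmark(small_scenario())$spectra$values), 15)
})

test_that("noiseless trajectories hit the measured start and end points", {
  traj <- with(list(), {
    set.seed(1)  # irrelevant: no stochastic terms below
    simulate_trajectories(noiseless())
  })
  at <- function(t, var) unique(traj$ph[traj$time_h == t & traj$variety == var])
  expect_equal(at(0, "Typica"), 5.60)
  expect_equal(at(0, "Caturra"), 5.43)
  expect_equal(at(0, "Catimor"), 5.57)
  expect_equal(at(24, "Typica"), 4.77)
  expect_equal(at(24, "Caturra"), 4.60)
  expect_equal(at(24, "Catimor"), 4.67)
  tss0 <- vapply(c("Typica", "Caturra", "Catimor"),
                 function(v) unique(traj$tss[traj$time_h == 0 & traj$variety == v]),
                 numeric(1))
  expect_equal(unname(tss0), c(15.87, 15.13, 16.53))
  # pH trajectories are monotone non-increasing over time
  for (v in c("Typica", "Caturra", "Catimor")) {
    ph_by_time <- vapply(sort(unique(traj$time_h)),
                         function(t) at(t, v)[1], numeric(1))
    expect_true(all(diff(ph_by_time) <= 0))
  }
})

test_that("infinite decay rate collapses to a step at t = 0+", {
  traj <- simulate_trajectories(noiseless(ph_rate = Inf, tss_rate = Inf))
  expect_equal(unique(traj$ph[traj$time_h == 4 & traj$variety == "Typica"]),
               4.77)
  expect_equal(unique(traj$ph[traj$time_h == 0 & traj$variety == "Typica"]),
               5.60)
})

test_that("non-physical scenarios are rejected", {
  expect_error(fermentation_scenario(ph_end = c(5.8, 4.6, 4.67)),
               "non-physical")
  expect_error(fermentation_scenario(bands = data.frame(
    center = 900, width = 10, amplitude = 0.1,
    ph_coupling = 0, tss_coupling = 0)), "within the wavelength range")
})

test_that("benchmarks are bit-identical under the same seed", {
  b1 <- make_benchmark(small_scenario(seed = 404))
  b2 <- make_benchmark(small_scenario(seed = 404))
  expect_identical(b1$spectra$values, b2$spectra$values)
  expect_identical(b1$ph$y, b2$ph$y)
  b3 <- make_benchmark(small_scenario(seed = 405))
  expect_false(identical(b1$spectra$values, b3$spectra$values))
})

test_that("a degenerate generator emits identical spectra", {
  sc <- noiseless(bands = data.frame(center = 1451, width = 22,
                                     amplitude = 0.3, ph_coupling = 0,
                                     tss_coupling = 0))
  b <- make_benchmark(sc)
  expect_lt(max(apply(b$spectra$values, 2, function(col) diff(range(col)))),
            1e-12)
})

test_that("the most pH-correlated wavelength sits on the coupled band", {
  bands <- data.frame(
    center = c(1205, 1451, 1729, 1839, 1927),
    width = c(18, 22, 16, 15, 24),
    amplitude = c(0.25, 0.45, 0.20, 0.15, 0.50),
    ph_coupling = c(0, -0.15, 0, 0, 0),     # only 1451 nm coupled
    tss_coupling = 0)
  b <- make_benchmark(fermentation_scenario(bands = bands, seed = 808))
  A <- reflectance_to_absorbance(b$spectra)
  cors <- abs(cor(A$values, b$ph$y))
  wl_star <- b$spectra$wavelengths[which.max(cors)]
  expect_lte(abs(wl_star - 1451), 22)
  # planted truth is confined to the coupled band support
  expect_true(all(b$truth$ph %in%
                    which(abs(b$spectra$wavelengths - 1451) <= 44)))
  expect_length(b$truth$tss, 0)
})

test_that("generated responses are non-normal mixtures over time points", {
  b <- make_benchmark(fermentation_scenario())
  d_ph <- ks_statistic(b$ph$y)$D
  d_tss <- ks_statistic(b$tss$y)$D
  crit <- 1.36 / sqrt(2100)         # asymptotic 5% Kolmogorov band
  expect_gt(d_ph, crit)
  expect_gt(d_tss, crit)
})

test_that("more reference noise degrades cross-validated accuracy", {
  r2_at <- function(noise) {
    sc <- fermentation_scenario(varieties = "Typica", subsamples = 1,
                                profiles = 10, ph_start = 5.6,
                                ph_end = 4.77, tss_start = 15.87,
                                tss_end = 12.87, ph_noise = noise,
                                seed = 909)
    pb <- prep_benchmark(sc, "ph")
    rep <- run_repeated_kfold(pb$ds$spectra$values, pb$ds$y,
                              plsr_recipe(ncomp = 6), K = 5, reps = 2,
                              base_seed = 21)
    unname(rep$aggregate$mean["r2"])
  }
  r2 <- vapply(c(0.02, 0.12, 0.4), r2_at, numeric(1))
  expect_true(all(diff(r2) < 0))
})
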