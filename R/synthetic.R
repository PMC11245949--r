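# Synthetic coffee-fermentation datasets: pH / TSS trajectories per
# variety and Beer-Lambert style NIR spectra with Gaussian absorption
# bands coupled to the responses. The generator emulates the structure
# of a three-variety, seven-time-point fermentation study (2 subsamples
# per time, 50 spectral profiles per sample = 2100 profiles), which is
# what makes every pipeline stage testable without laboratory data.

# default absorption bands: centres from the classic NIR assignments
# (C-H at 1205 and 1729 nm, O-H water at 1451 and 1927 nm, cellulose
# C-H at 1839 nm). Coupling columns give the absorbance change per unit
# of response; the water/acid bands track pH, the carbohydrate bands
# track TSS, 1839 nm is deliberately left uncoupled.
default_bands <- function() {
  data.frame(
    center = c(1205, 1451, 1729, 1839, 1927),
    width = c(18, 22, 16, 15, 24),            # Gaussian sigma, nm
    amplitude = c(0.25, 0.45, 0.20, 0.15, 0.50),
    ph_coupling = c(0, -0.15, 0, 0, -0.10),   # AU per pH unit
    tss_coupling = c(0.04, 0, 0.03, 0, 0)     # AU per degree Brix
  )
}

#' Define a fermentation simulation scenario
#'
#' The stated world of the generator: three arabica varieties sampled
#' at seven fermentation times (0-24 h) with two subsamples and 50
#' spectral profiles per sample; pH falls from the unfermented values
#' (5.60, 5.43, 5.57) to the 24 h values (4.77, 4.60, 4.67) along an
#' exponential decay that stabilizes after 16-20 h; TSS starts at
#' 15.87, 15.13 and 16.53 degrees Brix and drops by about 3 as sugars
#' are consumed. Spectra are built in absorbance space as a sloping
#' baseline plus Gaussian absorption bands whose amplitudes are coupled
#' to the responses, then converted to reflectance.
#'
#' @param varieties character vector of variety labels.
#' @param times fermentation times in hours.
#' @param subsamples subsamples per variety x time.
#' @param profiles spectral profiles per subsample.
#' @param ph_start,ph_end per-variety pH at the first and last time.
#' @param ph_rate exponential decay rate (1/h) of the pH trajectory;
#'   `Inf` gives a step to the end value.
#' @param tss_start,tss_end per-variety TSS (degrees Brix) endpoints.
#' @param tss_rate TSS decay rate (1/h).
#' @param ph_jitter,tss_jitter SD of the profile-level biological
#'   jitter (enters both the response and the spectrum).
#' @param ph_noise,tss_noise SD of the measurement noise on the
#'   recorded reference values (does not enter the spectrum; this is
#'   what bounds the attainable cross-validated R2).
#' @param bands data.frame of absorption bands (`center`, `width`,
#'   `amplitude`, `ph_coupling`, `tss_coupling`).
#' @param wavelengths nm axis (default 1100-2100 at 2 nm, 501 points).
#' @param baseline_intercept,baseline_slope absorbance baseline
#'   `b0 + b1 * (lambda - 1100) / 1000`.
#' @param drift_sd SD of the per-profile baseline offset (instrument
#'   drift).
#' @param noise_sd SD of the per-wavelength absorbance noise.
#' @param ph_ref,tss_ref reference levels at which band amplitudes
#'   equal their base values.
#' @param seed integer seed for [make_benchmark()].
#' @return object of class `fermentation_scenario`.
#' @export
fermentation_scenario <- function(
    varieties = c("Typica", "Caturra", "Catimor"),
    times = c(0, 4, 8, 12, 16, 20, 24),
    subsamples = 2,
    profiles = 50,
    ph_start = c(5.60, 5.43, 5.57),
    ph_end = c(4.77, 4.60, 4.67),
    ph_rate = 0.22,
    tss_start = c(15.87, 15.13, 16.53),
    tss_end = tss_start - 3,
    tss_rate = 0.18,
    ph_jitter = 0.03,
    tss_jitter = 0.15,
    ph_noise = 0.06,
    tss_noise = 0.22,
    bands = default_bands(),
    wavelengths = seq(1100, 2100, by = 2),
    baseline_intercept = 0.35,
    baseline_slope = 0.10,
    drift_sd = 0.01,
    noise_sd = 0.004,
    ph_ref = 5.0,
    tss_ref = 13.5,
    seed = 20240617) {
  nv <- length(varieties)
  stopifnot(length(ph_start) == nv, length(ph_end) == nv,
            length(tss_start) == nv, length(tss_end) == nv)
  if (any(ph_end > ph_start)) {
    stop("pH end above start is non-physical for fermentation", call. = FALSE)
  }
  if (any(bands$center < min(wavelengths)) ||
      any(bands$center > max(wavelengths))) {
    stop("band centers must lie within the wavelength range", call. = FALSE)
  }
  structure(
    list(varieties = varieties, times = times, subsamples = subsamples,
         profiles = profiles, ph_start = ph_start, ph_end = ph_end,
         ph_rate = ph_rate, tss_start = tss_start, tss_end = tss_end,
         tss_rate = tss_rate, ph_jitter = ph_jitter,
         tss_jitter = tss_jitter, ph_noise = ph_noise,
         tss_noise = tss_noise, bands = bands, wavelengths = wavelengths,
         baseline_intercept = baseline_intercept,
         baseline_slope = baseline_slope, drift_sd = drift_sd,
         noise_sd = noise_sd, ph_ref = ph_ref, tss_ref = tss_ref,
         seed = seed),
    class = "fermentation_scenario"
  )
}

#' @export
print.fermentation_scenario <- function(x, ...) {
  cat(sprintf("<fermentation_scenario> %d varieties x %d times x %d subsamples x %d profiles = %d rows\n",
              length(x$varieties), length(x$times), x$subsamples,
              x$profiles,
              length(x$varieties) * length(x$times) * x$subsamples * x$profiles))
  invisible(x)
}

# normalized exponential decay hitting start at t = 0 and end at t = T
# exactly; rate -> Inf collapses to a step at t = 0+.
decay_curve <- function(t, start, end, rate, t_max) {
  if (!is.finite(rate)) {
    return(ifelse(t == 0, start, end))
  }
  frac <- (exp(-rate * t) - exp(-rate * t_max)) / (1 - exp(-rate * t_max))
  end + (start - end) * frac
}

#' Simulate pH / TSS fermentation trajectories
#'
#' Produces one row per spectral profile with nominal, true (nominal +
#' biological jitter) and observed (true + measurement noise) pH and
#' TSS. With jitter and noise at zero the values are the exact decay
#' curves, hitting the configured start and end values at the first and
#' last time point.
#'
#' @param scenario a [fermentation_scenario].
#' @return data.frame with columns `sample_id`, `variety`, `time_h`,
#'   `subsample`, `replicate`, `ph`, `tss` (observed values) and
#'   `ph_true`, `tss_true` (the values the spectra respond to).
#'   Stochastic parts use the current RNG stream; seed externally (see
#'   [make_benchmark()]).
#' @export
simulate_trajectories <- function(scenario) {
  stopifnot(inherits(scenario, "fermentation_scenario"))
  sc <- scenario
  t_max <- max(sc$times)
  grid <- expand.grid(replicate = seq_len(sc$profiles),
                      subsample = seq_len(sc$subsamples),
                      time_h = sc$times,
                      variety = sc$varieties,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vi <- match(grid$variety, sc$varieties)
  ph_nom <- decay_curve(grid$time_h, sc$ph_start[vi], sc$ph_end[vi],
                        sc$ph_rate, t_max)
  tss_nom <- decay_curve(grid$time_h, sc$tss_start[vi], sc$tss_end[vi],
                         sc$tss_rate, t_max)
  nr <- nrow(grid)
  ph_true <- ph_nom + stats::rnorm(nr, 0, sc$ph_jitter)
  tss_true <- tss_nom + stats::rnorm(nr, 0, sc$tss_jitter)
  tss_true[tss_true < 0] <- 0
  data.frame(
    sample_id = sprintf("%s_t%02d_s%d_r%02d", grid$variety, grid$time_h,
                        grid$subsample, grid$replicate),
    variety = grid$variety, time_h = grid$time_h,
    subsample = grid$subsample, replicate = grid$replicate,
    ph = ph_true + stats::rnorm(nr, 0, sc$ph_noise),
    tss = pmax(tss_true + stats::rnorm(nr, 0, sc$tss_noise), 0),
    ph_true = ph_true, tss_true = tss_true,
    stringsAsFactors = FALSE
  )
}

#' Simulate NIR reflectance spectra from trajectories
#'
#' Builds each profile's absorbance as a sloping baseline (plus a
#' per-profile drift offset), Gaussian absorption bands whose
#' amplitudes respond linearly to the profile's true pH and TSS, and
#' white noise; reflectance is then `10^(-A)`. Reflectance outside
#' (0, 1] is clipped with a warning that counts the affected cells.
#'
#' @param scenario a [fermentation_scenario].
#' @param trajectories output of [simulate_trajectories()].
#' @return a [spectrum_set] in reflectance mode with the trajectory
#'   metadata attached.
#' @export
simulate_spectra <- function(scenario, trajectories) {
  stopifnot(inherits(scenario, "fermentation_scenario"))
  sc <- scenario
  wl <- sc$wavelengths
  p <- length(wl)
  nr <- nrow(trajectories)
  bands <- sc$bands
  nb <- nrow(bands)

  # band shapes (nb x p) and per-profile amplitudes (nr x nb)
  G <- t(vapply(seq_len(nb), function(b) {
    exp(-(wl - bands$center[b])^2 / (2 * bands$width[b]^2))
  }, numeric(p)))
  amps <- matrix(bands$amplitude, nr, nb, byrow = TRUE) +
    outer(trajectories$ph_true - sc$ph_ref, bands$ph_coupling) +
    outer(trajectories$tss_true - sc$tss_ref, bands$tss_coupling)

  baseline <- sc$baseline_intercept + sc$baseline_slope * (wl - 1100) / 1000
  A <- amps %*% G + matrix(baseline, nr, p, byrow = TRUE) +
    matrix(stats::rnorm(nr, 0, sc$drift_sd), nr, p) +   # per-profile drift
    matrix(stats::rnorm(nr * p, 0, sc$noise_sd), nr, p)

  R <- 10^(-A)
  n_clip <- sum(R > 1) + sum(R <= 0)
  if (n_clip > 0) {
    warning(sprintf("%d reflectance cells outside (0, 1] were clipped",
                    n_clip))
    R[R > 1] <- 1
    R[R <= 0] <- .Machine$double.eps
  }
  spectrum_set(R, wl, mode = "reflectance",
               sample_ids = trajectories$sample_id,
               metadata = trajectories[, c("variety", "time_h", "subsample",
                                           "replicate")])
}

#' Generate a reproducible benchmark dataset with planted truth
#'
#' Runs [simulate_trajectories()] and [simulate_spectra()] under the
#' scenario seed and returns the spectra, reference tables for pH and
#' TSS, and the planted ground truth: the wavelength indices within two
#' band widths of each response-coupled band centre. Two calls with the
#' same scenario are bit-identical.
#'
#' @param scenario a [fermentation_scenario].
#' @return list with `spectra` ([spectrum_set]), `ph` and `tss`
#'   ([reference_table]s), `trajectories`, and `truth`: list of index
#'   vectors `ph`, `tss` and `all` (union over both responses).
#' @export
make_benchmark <- function(scenario = fermentation_scenario()) {
  stopifnot(inherits(scenario, "fermentation_scenario"))
  out <- with_seed(scenario$seed, {
    traj <- simulate_trajectories(scenario)
    spectra <- simulate_spectra(scenario, traj)
    list(traj = traj, spectra = spectra)
  })
  wl <- scenario$wavelengths
  bands <- scenario$bands
  support <- function(coupled) {
    idx <- integer(0)
    for (b in which(coupled)) {
      idx <- c(idx, which(abs(wl - bands$center[b]) <= 2 * bands$width[b]))
    }
    sort(unique(idx))
  }
  truth <- list(ph = support(bands$ph_coupling != 0),
                tss = support(bands$tss_coupling != 0))
  truth$all <- sort(union(truth$ph, truth$tss))
  list(
    spectra = out$spectra,
    ph = reference_table(out$traj$sample_id, out$traj$ph, "pH"),
    tss = reference_table(out$traj$sample_id, out$traj$tss, "TSS"),
    trajectories = out$traj,
    truth = truth,
    scenario = scenario
  )
}

#' Small scenario for fast tests and examples
#'
#' One variety, three time points, one subsample, five profiles: a
#' 15-row dataset exercising every pipeline stage in well under a
#' second.
#'
#' @param ... overrides passed to [fermentation_scenario()].
#' @return a [fermentation_scenario].
#' @export
small_scenario <- function(...) {
  fermentation_scenario(
    varieties = "Typica", times = c(0, 12, 24), subsamples = 1,
    profiles = 5, ph_start = 5.60, ph_end = 4.77,
    tss_start = 15.87, tss_end = 12.87, ...)
}
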