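# Independent oracles and small fixture builders used across the suite.

# random regression instance with planted linear signal
make_instance <- function(n, p, beta = NULL, noise = 0.1, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    if (is.null(beta)) beta <- rnorm(p)
    y <- drop(X %*% beta) + rnorm(n, 0, noise)
    list(X = X, y = y, beta = beta)
  })
}

# ordinary least squares on centered data (normal equations)
ols_beta <- function(X, y) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  drop(solve(crossprod(Xc), crossprod(Xc, yc)))
}

# Savitzky-Golay oracle: smooth one interior point by explicitly
# fitting the local least-squares polynomial with lm()
sg_point_oracle <- function(signal, j, poly_order, m) {
  idx <- (j - m):(j + m)
  w <- signal[idx]
  x <- -m:m
  fit <- stats::lm(w ~ poly(x, poly_order, raw = TRUE))
  unname(stats::predict(fit, newdata = data.frame(x = 0)))
}

# brute-force covering-array checker: nested loops over all t-column
# subsets and all v^t symbol tuples
brute_force_coverage <- function(mat, t, v) {
  cols <- utils::combn(ncol(mat), t, simplify = FALSE)
  tuples <- as.matrix(expand.grid(rep(list(0:(v - 1)), t)))
  for (cc in cols) {
    sub <- mat[, cc, drop = FALSE]
    for (ti in seq_len(nrow(tuples))) {
      hit <- FALSE
      for (r in seq_len(nrow(sub))) {
        if (all(sub[r, ] == tuples[ti, ])) { hit <- TRUE; break }
      }
      if (!hit) return(list(covered = FALSE, columns = cc,
                            tuple = unname(tuples[ti, ])))
    }
  }
  list(covered = TRUE)
}

# Kolmogorov-Smirnov oracle: sup |F_n - F| over a dense grid that
# includes both sides of every ECDF jump
ks_oracle <- function(x, mean, sd) {
  Fn <- stats::ecdf(x)
  grid <- sort(c(x, x - 1e-12,
                 seq(min(x) - 4 * sd, max(x) + 4 * sd, length.out = 2e5)))
  max(abs(Fn(grid) - stats::pnorm(grid, mean, sd)))
}

# preprocessed benchmark dataset (absorbance + SG window 7), joined
prep_benchmark <- function(scenario, response = c("ph", "tss")) {
  response <- match.arg(response)
  b <- make_benchmark(scenario)
  ref <- if (response == "ph") b$ph else b$tss
  a <- sg_smooth(reflectance_to_absorbance(b$spectra), window = 7)
  ds <- join_dataset(a, ref)
  list(ds = ds, truth = b$truth, bench = b)
}
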