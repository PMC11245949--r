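# Model assessment: R2 / RMSE / RPD metrics, the repeated K-fold
# protocol, the Kolmogorov-Smirnov statistic, and full-vs-optimized
# model comparison tables.

#' Prediction metrics: R2, RMSE and RPD
#'
#' `RMSE = sqrt(mean((yhat - y)^2))`; `R2 = 1 - SSE / SST` with the
#' standard total sum of squares `sum((y - mean(y))^2)` (set
#' `r2_method = "predicted-mean"` for the variant that normalizes by
#' `sum((yhat - mean(y))^2)`, kept selectable for audit); `RPD = SD /
#' RMSE`, the ratio of performance to deviation. A perfect fit has
#' RMSE 0 and its RPD is reported as `Inf` with `rpd_infinite = TRUE`.
#'
#' @param y_true,y_pred equal-length finite numeric vectors, `n >= 2`.
#' @param sd_reference standard deviation used in the RPD numerator;
#'   defaults to the population (n-divisor) SD of `y_true`. Pass the SD
#'   of the full response vector when scoring a held-out fold, so RPD
#'   is comparable across folds.
#' @param r2_method `"standard"` or `"predicted-mean"`.
#' @return object of class `metric_set`: list with `r2`, `rmse`, `rpd`,
#'   `n`, `sd` and `rpd_infinite`.
#' @export
compute_metrics <- function(y_true, y_pred, sd_reference = NULL,
                            r2_method = c("standard", "predicted-mean")) {
  r2_method <- match.arg(r2_method)
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length", call. = FALSE)
  }
  n <- length(y_true)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred))) {
    stop("inputs must be finite", call. = FALSE)
  }
  sse <- sum((y_pred - y_true)^2)
  ym <- mean(y_true)
  sst <- if (r2_method == "standard") sum((y_true - ym)^2)
         else sum((y_pred - ym)^2)
  if (sst == 0) stop("zero-variance denominator in R2", call. = FALSE)
  rmse <- sqrt(sse / n)
  if (is.null(sd_reference)) sd_reference <- sd_pop(y_true)
  rpd_infinite <- rmse == 0
  rpd <- if (rpd_infinite) Inf else sd_reference / rmse
  structure(list(r2 = 1 - sse / sst, rmse = rmse, rpd = rpd, n = n,
                 sd = sd_reference, rpd_infinite = rpd_infinite),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> R2=%.4f RMSE=%.4g RPD=%.3g (n=%d)\n",
              x$r2, x$rmse, x$rpd, x$n))
  invisible(x)
}

#' Reproducible K-fold assignment
#'
#' Randomly assigns `n` samples to `K` folds of near-equal size; every
#' sample lands in exactly one fold. Deterministic given the seed.
#'
#' @param n sample count, `n >= K`.
#' @param K number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels in `1..K`.
#' @export
make_folds <- function(n, K, seed) {
  K <- as.integer(K)
  if (n < K) stop("need n >= K", call. = FALSE)
  with_seed(seed, sample(rep_len(seq_len(K), n)))
}

#' PLSR model recipe for cross-validation
#'
#' Bundles everything that must happen inside a training fold: optional
#' wavelength selection, optional component-count search, and the PLSR
#' fit. Passing a `selector` makes selection part of the recipe, so it
#' is re-run on each training fold and the held-out fold never
#' influences it.
#'
#' @param ncomp fixed component count, or `NULL` to choose it per fold
#'   by inner cross-validation over `1..ncomp_max` ([choose_ncomp()]).
#' @param ncomp_max upper bound of the component search (default 15).
#' @param selector optional `function(X, y, seed)` returning a
#'   `selection_result` (or an integer index vector) computed on the
#'   training fold.
#' @param label recipe label used in comparison tables.
#' @return object of class `model_recipe` with `$fit(X, y, seed)`
#'   returning a fitted object carrying `$predict(Xnew)` and
#'   `$n_variables`.
#' @export
plsr_recipe <- function(ncomp = 10, ncomp_max = 15, selector = NULL,
                        label = "plsr") {
  force(ncomp); force(ncomp_max); force(selector)
  fit_fun <- function(X, y, seed) {
    cols <- seq_len(ncol(X))
    if (!is.null(selector)) {
      sel <- selector(X, y, seed)
      cols <- if (inherits(sel, "selection_result")) sel$indices
              else as.integer(sel)
    }
    Xs <- X[, cols, drop = FALSE]
    a <- if (is.null(ncomp)) {
      choose_ncomp(Xs, y, ncomp_max = ncomp_max, seed = seed)$ncomp
    } else {
      min(ncomp, ncol(Xs), nrow(Xs) - 1L)
    }
    model <- fit_plsr(Xs, y, ncomp = a)
    list(predict = function(Xnew) predict(model, Xnew[, cols, drop = FALSE]),
         n_variables = length(cols), ncomp = a, model = model)
  }
  structure(list(fit = fit_fun, label = label,
                 has_selector = !is.null(selector)),
            class = "model_recipe")
}

# Fold-level metrics tolerant of degenerate folds: a single held-out
# sample (the leave-one-out limit) or a constant y_true leaves R2
# undefined (NA) while RMSE and RPD are still well defined.
fold_metrics <- function(y_true, y_pred, sd_reference) {
  n <- length(y_true)
  if (n >= 2 && sum((y_true - mean(y_true))^2) > 0) {
    m <- compute_metrics(y_true, y_pred, sd_reference = sd_reference)
    return(list(r2 = m$r2, rmse = m$rmse, rpd = m$rpd, n = n))
  }
  rmse <- sqrt(mean((y_pred - y_true)^2))
  list(r2 = NA_real_, rmse = rmse, n = n,
       rpd = if (rmse == 0) Inf else sd_reference / rmse)
}

#' Repeated K-fold cross-validation
#'
#' Runs the evaluation protocol: `reps` independent K-fold splits
#' (default K = 5, 30 repetitions); within each repetition every sample
#' is held out exactly once; metrics (R2, RMSE, RPD) are computed on
#' each held-out fold with the RPD standard deviation taken from the
#' full response vector. Fold assignments for repetition `r` derive
#' from `base_seed + r - 1` and are stored, so any report is bit
#' reproducible from its base seed.
#'
#' @param X sample x wavelength matrix (or an `nir_dataset`, in which
#'   case `y` is taken from it).
#' @param y response vector.
#' @param recipe a [plsr_recipe()].
#' @param K folds per repetition (default 5).
#' @param reps repetitions (default 30).
#' @param base_seed integer seed; repetition `r` uses
#'   `base_seed + r - 1`.
#' @return object of class `cv_report`: per-cell data.frame `cells`
#'   (rep, fold, r2, rmse, rpd, n, ncomp, n_variables), `aggregate`
#'   (means and SDs over all cells), `folds` (n x reps assignment
#'   matrix), `seeds`, and the protocol parameters.
#' @export
run_repeated_kfold <- function(X, y = NULL, recipe = plsr_recipe(),
                               K = 5, reps = 30, base_seed = 1) {
  if (inherits(X, "nir_dataset")) {
    y <- X$y
    X <- X$spectra$values
  }
  X <- check_finite_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < K) stop("need n >= K", call. = FALSE)
  stopifnot(inherits(recipe, "model_recipe"))
  sd_full <- sd_pop(y)
  seeds <- base_seed + seq_len(reps) - 1L

  cells <- vector("list", reps * K)
  fold_mat <- matrix(NA_integer_, n, reps)
  for (r in seq_len(reps)) {
    folds <- make_folds(n, K, seeds[r])
    fold_mat[, r] <- folds
    for (k in seq_len(K)) {
      tr <- folds != k
      fitted <- recipe$fit(X[tr, , drop = FALSE], y[tr], seed = seeds[r])
      pred <- fitted$predict(X[!tr, , drop = FALSE])
      m <- fold_metrics(y[!tr], pred, sd_full)
      cells[[(r - 1) * K + k]] <- data.frame(
        rep = r, fold = k, r2 = m$r2, rmse = m$rmse, rpd = m$rpd,
        n = m$n, ncomp = fitted$ncomp, n_variables = fitted$n_variables)
    }
  }
  cells <- do.call(rbind, cells)
  aggregate <- list(
    mean = c(r2 = mean(cells$r2, na.rm = TRUE), rmse = mean(cells$rmse),
             rpd = mean(cells$rpd)),
    sd = c(r2 = stats::sd(cells$r2, na.rm = TRUE),
           rmse = stats::sd(cells$rmse), rpd = stats::sd(cells$rpd)),
    n_variables = mean(cells$n_variables)
  )
  structure(
    list(cells = cells, aggregate = aggregate, folds = fold_mat,
         seeds = seeds, K = K, reps = reps, base_seed = base_seed,
         label = recipe$label, n = n, sd = sd_full),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  m <- x$aggregate$mean
  cat(sprintf("<cv_report> %s: K=%d x %d reps, R2=%.3f RMSE=%.4g RPD=%.3g\n",
              x$label, x$K, x$reps, m["r2"], m["rmse"], m["rpd"]))
  invisible(x)
}

#' Kolmogorov-Smirnov statistic against a fitted normal
#'
#' Computes `D = max(D+, D-)` with `D+ = max_i(i/n - Z_i)`,
#' `D- = max_i(Z_i - (i-1)/n)` and `Z_i = F(X_(i))`, where `F` is the
#' normal CDF. By default the normal parameters are the maximum
#' likelihood fit (sample mean and population SD) of `x`; pass `mean`
#' and `sd` to test against a fixed normal instead. For `n = 1` with
#' fitted parameters the convention `Z = 0.5` (the point sits at the
#' fitted median) is used.
#'
#' @param x finite numeric sample, `n >= 1`.
#' @param mean,sd optional fixed normal parameters.
#' @return object of class `ks_result`: `D`, `D_plus`, `D_minus`, `n`
#'   and the normal parameters used.
#' @export
ks_statistic <- function(x, mean = NULL, sd = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 1 || any(!is.finite(x))) stop("x must be a finite sample",
                                        call. = FALSE)
  fitted <- is.null(mean) || is.null(sd)
  if (is.null(mean)) mean <- base::mean(x)
  if (is.null(sd)) {
    if (n == 1) {
      sd <- NA_real_           # Z = 0.5 convention below
    } else {
      sd <- sd_pop(x)
      if (sd == 0) stop("zero sample standard deviation", call. = FALSE)
    }
  } else if (sd <= 0) {
    stop("sd must be positive", call. = FALSE)
  }
  xs <- sort(x)
  Z <- if (n == 1 && is.na(sd)) 0.5 else stats::pnorm(xs, mean, sd)
  i <- seq_len(n)
  d_plus <- max(i / n - Z)
  d_minus <- max(Z - (i - 1) / n)
  structure(list(D = max(d_plus, d_minus), D_plus = d_plus,
                 D_minus = d_minus, n = n, mean = mean, sd = sd,
                 fitted = fitted),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D=%.4f (D+=%.4f, D-=%.4f), n=%d\n",
              x$D, x$D_plus, x$D_minus, x$n))
  invisible(x)
}

#' Compare full-spectrum and optimized models
#'
#' Builds a comparison table (one row per model) of aggregated R2,
#' RMSE and RPD, plus the mean number of variables used. All reports
#' must come from the same protocol: identical K, repetitions and base
#' seed, hence identical fold assignments.
#'
#' @param full `cv_report` of the full-spectrum model.
#' @param optimized named list of `cv_report`s for the selection
#'   methods (may be empty).
#' @return data.frame with columns `model`, `r2`, `rmse`, `rpd`,
#'   `n_variables`.
#' @export
compare_models <- function(full, optimized = list()) {
  stopifnot(inherits(full, "cv_report"))
  reports <- c(list(full = full), optimized)
  for (rep_i in reports) {
    stopifnot(inherits(rep_i, "cv_report"))
    if (rep_i$K != full$K || rep_i$reps != full$reps ||
        rep_i$base_seed != full$base_seed || rep_i$n != full$n) {
      stop("reports were not built with matching fold seeds", call. = FALSE)
    }
  }
  nm <- names(reports)
  if (is.null(nm)) nm <- vapply(reports, `[[`, "", "label")
  do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(model = nm[i],
               r2 = r$aggregate$mean["r2"],
               rmse = r$aggregate$mean["rmse"],
               rpd = r$aggregate$mean["rpd"],
               n_variables = r$aggregate$n_variables,
               row.names = NULL)
  }))
}
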