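# Wavelength selection: beta-coefficient ranking, VIP thresholding and
# covering-array feature selection (CAFS).

#' Construct a selection result
#'
#' Common container for the three wavelength selectors: the sorted
#' selected column indices (1-based), a per-wavelength score vector,
#' the method tag and its parameters, and the seed (when the method is
#' stochastic).
#'
#' @param method method tag (`"beta"`, `"vip"`, `"cafs"`).
#' @param indices integer vector of selected column indices.
#' @param scores numeric per-wavelength score vector of length `p`.
#' @param params list of selection parameters.
#' @param seed seed used, or `NA` for deterministic selectors.
#' @return object of class `selection_result`.
#' @export
selection_result <- function(method, indices, scores, params = list(),
                             seed = NA_integer_) {
  indices <- sort(unique(as.integer(indices)))
  p <- length(scores)
  if (length(indices) == 0) {
    stop_with_class("selection is empty", "cafspec_empty_selection")
  }
  if (any(indices < 1) || any(indices > p)) {
    stop("selected indices outside [1, p]", call. = FALSE)
  }
  if (any(!is.finite(scores[indices]))) {
    stop("selected index with non-finite score", call. = FALSE)
  }
  structure(list(method = method, indices = indices, scores = scores,
                 params = params, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method=%s, %d of %d wavelengths selected\n",
              x$method, length(x$indices), length(x$scores)))
  invisible(x)
}

#' Write a selection result as delimited text
#'
#' One row per selected wavelength: index, wavelength (nm, when a
#' wavelength axis is supplied) and score.
#'
#' @param sel a `selection_result`.
#' @param path output file path.
#' @param wavelengths optional nm axis of length `p`.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path, wavelengths = NULL) {
  stopifnot(inherits(sel, "selection_result"))
  df <- data.frame(index = sel$indices,
                   wavelength_nm = if (is.null(wavelengths)) NA_real_
                                   else wavelengths[sel$indices],
                   score = sel$scores[sel$indices])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select wavelengths by regression-coefficient magnitude
#'
#' Keeps the `n_keep` wavelengths with the largest absolute PLSR
#' regression coefficients. Ties are broken in favour of the lower
#' index, so the output is deterministic. The default count of 15
#' matches the constant cardinality this ranking tends to be used with
#' in fermentation NIRS work.
#'
#' @param model a fitted `plsr_model`.
#' @param n_keep number of wavelengths to keep, `1 <= n_keep <= p`.
#' @return a `selection_result` with scores `|beta_j|`.
#' @export
select_by_beta <- function(model, n_keep = 15) {
  stopifnot(inherits(model, "plsr_model"))
  p <- model$p
  n_keep <- as.integer(n_keep)
  if (n_keep < 1 || n_keep > p) {
    stop(sprintf("n_keep must lie in [1, %d]", p), call. = FALSE)
  }
  scores <- abs(model$coefficients)
  ord <- order(-scores, seq_len(p))   # ties -> lower index first
  selection_result("beta", ord[seq_len(n_keep)], scores,
                   params = list(n_keep = n_keep))
}

#' Select wavelengths by VIP threshold
#'
#' Keeps wavelengths whose VIP score strictly exceeds the threshold
#' (default 1, the conventional informativeness cutoff). An empty
#' selection raises a condition of class `cafspec_empty_selection`
#' rather than silently returning everything.
#'
#' @param vip a `vip_result` from [compute_vip()].
#' @param threshold positive cutoff; strict inequality is used.
#' @return a `selection_result` with scores `v_j`.
#' @export
select_by_vip <- function(vip, threshold = 1) {
  stopifnot(inherits(vip, "vip_result"))
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  idx <- which(vip$vip > threshold)
  if (length(idx) == 0) {
    stop_with_class(
      sprintf("no VIP score exceeds the threshold %.3g", threshold),
      "cafspec_empty_selection")
  }
  selection_result("vip", idx, vip$vip, params = list(threshold = threshold))
}

# K-fold cross-validated RMSE of a PLSR fit on X[, cols]; the fold
# assignment is supplied so every CAFS row is scored on the same folds.
cv_rmse_plsr <- function(X, y, folds, ncomp) {
  K <- max(folds)
  rmse <- numeric(K)
  for (k in seq_len(K)) {
    tr <- folds != k
    a <- min(ncomp, sum(tr) - 1L, ncol(X))
    fit <- fit_plsr(X[tr, , drop = FALSE], y[tr], ncomp = a)
    pred <- predict(fit, X[!tr, , drop = FALSE])
    rmse[k] <- sqrt(mean((pred - y[!tr])^2))
  }
  mean(rmse)
}

#' Covering-array feature selection (CAFS)
#'
#' Screens spectral bands with a strength-`t` binary covering array and
#' keeps the wavelengths of the band subset that predicts best under
#' cross-validation. The procedure:
#'
#' 1. partition the `p` wavelengths into `n_bands` contiguous bands
#'    (contiguity reflects that NIR absorption features span adjacent
#'    wavelengths);
#' 2. build `CA(N; t, n_bands, 2)` with the greedy constructor; symbol
#'    1 in a row means "band included";
#' 3. for every CA row, fit PLSR on the included wavelengths and record
#'    its K-fold cross-validated RMSE (rows with no included band are
#'    skipped and logged);
#' 4. score each band as mean RMSE of the rows excluding it minus mean
#'    RMSE of the rows including it — a main-effects screening
#'    estimate, reported as the per-wavelength score and usable for a
#'    permutation null;
#' 5. retain the bands included in the best (lowest-RMSE) row, refit
#'    PLSR on their wavelengths with a deliberately parsimonious
#'    component count (`refit_ncomp`), rank those wavelengths by
#'    `|beta|` and keep the top `n_final`.
#'
#' The two-level alphabet encodes include/exclude; the maximal coverage
#' of the array guarantees every t-way include/exclude combination of
#' bands is observed at least once with few model evaluations.
#' Retention goes through the best row rather than the positively
#' scored bands because NIR absorption features span several contiguous
#' bands: with redundant copies of a feature present in almost every
#' row, single-band main effects shrink towards zero while whole-subset
#' performance still identifies informative regions. The low-rank refit
#' likewise keeps the `|beta|` ranking on the dominant predictive
#' factors instead of noise-inflated minor components.
#'
#' @param X sample x wavelength matrix (preprocessed absorbance).
#' @param y response vector aligned to `X` rows.
#' @param t covering-array strength (default 2).
#' @param n_bands number of contiguous bands (default 50).
#' @param n_final number of wavelengths finally kept (default 30).
#' @param ncomp PLSR components for the screening fits (default 10,
#'   capped by the data dimensions).
#' @param refit_ncomp components of the final ranking refit (default
#'   2; fermentation progress drives one or two latent factors).
#' @param cv_folds folds for the per-row RMSE (default 3).
#' @param seed integer seed; the whole procedure is deterministic given
#'   the seed.
#' @return a `selection_result`; `scores` carries each band's
#'   exclusion-inclusion RMSE gap replicated over its member
#'   wavelengths, and `params` records the CA dimensions, the best
#'   row, the retained bands and any skipped rows.
#' @export
cafs_select <- function(X, y, t = 2, n_bands = 50, n_final = 30,
                        ncomp = 10, refit_ncomp = 2, cv_folds = 3,
                        seed = 1) {
  X <- check_finite_matrix(X)
  p <- ncol(X); n <- nrow(X)
  n_bands <- as.integer(n_bands)
  if (n_bands > p) stop("n_bands cannot exceed the wavelength count",
                        call. = FALSE)
  if (n_bands < t) stop("need n_bands >= t", call. = FALSE)
  bands <- split(seq_len(p), cut(seq_len(p), n_bands, labels = FALSE))

  ca <- build_covering_array(t, k = n_bands, v = 2, seed = seed)
  folds <- make_folds(n, cv_folds, seed = seed)

  rmse <- rep(NA_real_, ca$N)
  skipped <- integer(0)
  for (r in seq_len(ca$N)) {
    inc <- which(ca$matrix[r, ] == 1L)
    if (length(inc) == 0) {         # degenerate all-exclude row
      skipped <- c(skipped, r)
      next
    }
    cols <- unlist(bands[inc], use.names = FALSE)
    rmse[r] <- cv_rmse_plsr(X[, cols, drop = FALSE], y, folds, ncomp)
  }
  ok <- !is.na(rmse)

  band_score <- vapply(seq_len(n_bands), function(b) {
    inc_rows <- ok & ca$matrix[, b] == 1L
    exc_rows <- ok & ca$matrix[, b] == 0L
    if (!any(inc_rows) || !any(exc_rows)) return(NA_real_)
    mean(rmse[exc_rows]) - mean(rmse[inc_rows])
  }, numeric(1))

  if (all(is.na(band_score)) ||
      all(band_score[!is.na(band_score)] <= 0)) {
    stop_with_class("no band improved cross-validated RMSE",
                    "cafspec_no_informative_band")
  }
  best_row <- which.min(rmse)        # ties -> first (deterministic)
  retained <- which(ca$matrix[best_row, ] == 1L)

  cols_ret <- unlist(bands[retained], use.names = FALSE)
  a_final <- min(refit_ncomp, length(cols_ret), n - 1L)
  refit <- fit_plsr(X[, cols_ret, drop = FALSE], y, ncomp = a_final)
  ord <- order(-abs(refit$coefficients), seq_along(cols_ret))
  keep <- cols_ret[ord[seq_len(min(n_final, length(cols_ret)))]]

  scores <- rep(NA_real_, p)
  for (b in seq_len(n_bands)) scores[bands[[b]]] <- band_score[b]

  selection_result(
    "cafs", keep, scores,
    params = list(t = t, v = 2, N = ca$N, n_bands = n_bands,
                  n_final = n_final, ncomp = ncomp,
                  refit_ncomp = refit_ncomp, cv_folds = cv_folds,
                  best_row = best_row, retained_bands = retained,
                  skipped_rows = skipped, band_score = band_score,
                  row_rmse = rmse),
    seed = seed
  )
}
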