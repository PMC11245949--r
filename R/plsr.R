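# Single-response partial least squares regression via NIPALS.
#
# For a single response the NIPALS weight step has a closed form
# (w = X'y / ||X'y||), so the decomposition is deterministic and
# non-iterative: one pass per latent component. Deflation of X after
# each component gives mutually orthogonal scores; the regression
# coefficients on the original predictors are recovered through
# B = W (P'W)^{-1} q.

#' Fit a PLSR model
#'
#' Fits single-response partial least squares regression with `ncomp`
#' latent components using the deterministic NIPALS decomposition.
#' Predictors and response are mean-centered internally; unit-variance
#' scaling is optional and off by default because absorbance spectra
#' share units and autoscaling would inflate noise bands.
#'
#' @param X sample x wavelength numeric matrix.
#' @param y numeric response vector.
#' @param ncomp number of latent components `A`, with
#'   `1 <= A <= min(n - 1, p)`.
#' @param scale logical; divide columns by their standard deviation
#'   before decomposition (default `FALSE`, mean-centering only).
#' @return an object of class `plsr_model` with weights `W` (columns of
#'   unit norm), scores `Tm`, X-loadings `P`, y-loadings `q`,
#'   per-component explained sum of squares of y `ss`, the coefficient
#'   path `coef_path` (column `a` = coefficients using `a` components),
#'   final `coefficients` and `intercept`, and the centering/scaling
#'   vectors.
#' @export
fit_plsr <- function(X, y, ncomp, scale = FALSE) {
  X <- check_finite_matrix(X)
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (p < 1) stop("X must have at least one column", call. = FALSE)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1) stop("ncomp must be >= 1", call. = FALSE)
  if (ncomp > min(n - 1L, p)) {
    stop(sprintf("ncomp = %d exceeds the rank bound min(n - 1, p) = %d",
                 ncomp, min(n - 1L, p)), call. = FALSE)
  }
  y_center <- mean(y)
  yc <- y - y_center
  if (sum(yc^2) == 0) stop("y has zero variance", call. = FALSE)
  x_center <- colMeans(X)
  x_scale <- rep(1, p)
  if (scale) {
    x_scale <- apply(X, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
  }
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, `/`)

  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  ss <- numeric(ncomp)
  Xd <- Xc
  yd <- yc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop(sprintf("ncomp = %d exceeds the effective rank (X'y vanished at component %d)",
                   ncomp, a), call. = FALSE)
    }
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    q[a] <- q_a
    ss[a] <- q_a^2 * tt       # SS of y explained by component a
  }

  # coefficients on the centered/scaled predictors, for each truncation
  R <- W %*% solve(t(P) %*% W)      # (P'W) is unit upper-triangular
  coef_path <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    coef_path[, a] <- R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)]
  }
  coef_path <- coef_path / x_scale  # back to the original X scale
  beta <- coef_path[, ncomp]
  intercepts <- y_center - drop(crossprod(x_center, coef_path))

  structure(
    list(ncomp = ncomp, W = W, P = P, Tm = Tm, q = q, ss = ss,
         coefficients = beta, intercept = intercepts[ncomp],
         coef_path = coef_path, intercept_path = intercepts,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         scaled = scale, p = p, n = n),
    class = "plsr_model"
  )
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d components, %d predictors, n = %d\n",
              x$ncomp, x$p, x$n))
  invisible(x)
}

#' Predict from a PLSR model
#'
#' @param object a fitted [fit_plsr()] model.
#' @param newdata matrix (or vector) with the training wavelength count.
#' @param ncomp number of components to use; defaults to the fitted
#'   count. Any `a <= object$ncomp` is available from the stored
#'   coefficient path.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- check_finite_matrix(newdata, "newdata")
  if (ncol(newdata) != object$p) {
    stop(sprintf("newdata has %d columns; model was trained on %d wavelengths",
                 ncol(newdata), object$p), call. = FALSE)
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > object$ncomp) {
    stop("ncomp outside the fitted component range", call. = FALSE)
  }
  drop(newdata %*% object$coef_path[, ncomp]) + object$intercept_path[ncomp]
}

#' Fitted values of a PLSR model reconstructed from the score space
#'
#' In-sample predictions computed directly from scores and y-loadings
#' (`y_center + T q`), used to verify that the coefficient form
#' `X beta + intercept` reproduces the latent-space regression.
#'
#' @param model a `plsr_model`.
#' @param ncomp components to use.
#' @return numeric vector of fitted values.
#' @export
fitted_from_scores <- function(model, ncomp = model$ncomp) {
  model$y_center +
    drop(model$Tm[, seq_len(ncomp), drop = FALSE] %*% model$q[seq_len(ncomp)])
}

#' Variable importance in projection (VIP)
#'
#' Computes the VIP score of each predictor:
#' `v_j = sqrt( p * sum_a SS_a (w_aj / ||w_a||)^2 / sum_a SS_a )`,
#' where `SS_a` is the response sum of squares explained by component
#' `a` and `w_a` the (unit-norm) X-weights. The scores satisfy
#' `sum_j v_j^2 = p`; predictors with VIP above 1 are conventionally
#' regarded as informative.
#'
#' @param model a fitted `plsr_model`.
#' @param threshold informativeness cutoff stored with the result
#'   (default 1).
#' @return an object of class `vip_result` with fields `vip` and
#'   `threshold`.
#' @export
compute_vip <- function(model, threshold = 1) {
  stopifnot(inherits(model, "plsr_model"))
  ss <- model$ss
  if (sum(ss) <= 0) stop("total explained sum of squares is zero", call. = FALSE)
  # W columns have unit norm, so (w_aj/||w_a||)^2 = W^2
  v <- sqrt(model$p * drop(model$W^2 %*% ss) / sum(ss))
  structure(list(vip = v, threshold = threshold), class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("<vip_result> p = %d, %d above threshold %.3g\n",
              length(x$vip), sum(x$vip > x$threshold), x$threshold))
  invisible(x)
}

#' Choose the PLSR component count by inner cross-validation
#'
#' Scans `A` in `1..ncomp_max` (capped by the rank bound) and returns
#' the count minimizing mean K-fold cross-validated RMSE. Intended to
#' be run inside training folds only, so test folds never influence the
#' choice.
#'
#' @param X,y training predictors and response.
#' @param ncomp_max largest component count to try (default 15).
#' @param K inner folds (default 5).
#' @param seed seed for the inner fold assignment.
#' @return list with `ncomp` (the argmin) and `rmse` (per-A mean CV
#'   RMSE).
#' @export
choose_ncomp <- function(X, y, ncomp_max = 15, K = 5, seed = 1) {
  X <- check_finite_matrix(X)
  n <- nrow(X)
  amax <- min(as.integer(ncomp_max), ncol(X), n - n %/% K - 1L)
  if (amax < 1) amax <- 1L
  folds <- make_folds(n, K, seed)
  press <- matrix(NA_real_, K, amax)
  for (k in seq_len(K)) {
    tr <- folds != k
    a_fit <- min(amax, sum(tr) - 1L, ncol(X))
    fit <- fit_plsr(X[tr, , drop = FALSE], y[tr], ncomp = a_fit)
    for (a in seq_len(a_fit)) {
      pred <- predict(fit, X[!tr, , drop = FALSE], ncomp = a)
      press[k, a] <- sqrt(mean((pred - y[!tr])^2))
    }
  }
  rmse <- colMeans(press)
  list(ncomp = which.min(rmse), rmse = rmse)
}
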