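# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so package functions never clobber the caller's
#' random stream. All stochastic stages in the package route their
#' randomness through this helper, which is what makes results
#' reproducible from the recorded seeds.
#'
#' @param seed integer seed (must be a finite scalar below 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (abs(seed) >= 2^31) {
    stop("seed must fit in a 32-bit integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Population (n-divisor) standard deviation; the RPD convention used
# throughout the package.
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

stop_with_class <- function(message, class) {
  stop(errorCondition(message, class = c(class, "cafspec_error")))
}

check_finite_matrix <- function(X, what = "X") {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X))) {
    stop(sprintf("%s must be a numeric matrix with finite entries", what),
         call. = FALSE)
  }
  X
}
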