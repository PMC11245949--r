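# Covering arrays CA(N; t, k, v): N x k matrices over {0..v-1} such
# that every selection of t columns exhibits all v^t symbol tuples in
# at least one row. Built with a seeded one-row-at-a-time greedy
# constructor (each new row chosen among candidates to maximize newly
# covered tuples), which gives the O(log k) row growth expected of
# greedy CA construction at fixed t and v.
#
# Tuple bookkeeping is by explicit enumeration, so strength is limited
# to t <= 3 — all the CAFS selector needs.

# all t-subsets of columns as a (choose(k,t) x t) matrix
.column_tuples <- function(k, t) {
  t(utils::combn(k, t))
}

# encode the symbols of each column tuple of a row as a base-v integer
.tuple_codes <- function(row, tuples, v) {
  code <- row[tuples[, 1]]
  if (ncol(tuples) > 1) {
    for (j in 2:ncol(tuples)) code <- code * v + row[tuples[, j]]
  }
  code + 1L   # 1-based index into the coverage table
}

#' Build a covering array with the greedy density heuristic
#'
#' Constructs a CA(N; t, k, v): rows are appended one at a time, each
#' chosen among seeded random candidates (plus the complement of the
#' previous row when v = 2) to maximize the number of newly covered
#' column-tuple/symbol-tuple pairs. The result always passes
#' [verify_coverage()]; N is whatever the heuristic needed, not a
#' proven minimum.
#'
#' @param t strength, `1 <= t <= min(k, 3)`.
#' @param k number of columns.
#' @param v alphabet size, `>= 2`.
#' @param seed integer seed; construction is deterministic given the
#'   seed.
#' @param n_candidates candidate rows scored per appended row.
#' @return an object of class `covering_array` with the `N x k` matrix
#'   over `{0..v-1}` and fields `t`, `v`, `N`, `k`, `method`, `seed`.
#' @export
build_covering_array <- function(t, k, v = 2, seed = 1, n_candidates = 50) {
  t <- as.integer(t); k <- as.integer(k); v <- as.integer(v)
  if (t < 1 || t > k) stop("need 1 <= t <= k", call. = FALSE)
  if (v < 2) stop("alphabet size v must be >= 2", call. = FALSE)
  if (t > 3) stop("strength t > 3 is not supported", call. = FALSE)

  tuples <- .column_tuples(k, t)
  n_tuples <- nrow(tuples)
  n_codes <- v^t
  covered <- matrix(FALSE, n_tuples, n_codes)
  rows <- list()

  with_seed(seed, {
    # seed the array with the constant rows: for t = 1 they finish the
    # job outright, and for v = 2 they cover the all-equal tuples cheaply
    for (sym in 0:(v - 1L)) {
      row <- rep(sym, k)
      codes <- .tuple_codes(row, tuples, v)
      new <- !covered[cbind(seq_len(n_tuples), codes)]
      if (any(new)) {
        covered[cbind(seq_len(n_tuples), codes)[new, , drop = FALSE]] <- TRUE
        rows[[length(rows) + 1L]] <- row
      }
      if (all(covered)) break
    }
    guard <- 0L
    while (!all(covered)) {
      guard <- guard + 1L
      if (guard > 10000L) stop("greedy constructor failed to converge")
      cand <- matrix(sample.int(v, n_candidates * k, replace = TRUE) - 1L,
                     n_candidates, k)
      if (v == 2L && length(rows) > 0) {
        cand <- rbind(cand, 1L - rows[[length(rows)]])
      }
      best_gain <- -1L; best_idx <- NULL
      for (i in seq_len(nrow(cand))) {
        codes <- .tuple_codes(cand[i, ], tuples, v)
        idx <- cbind(seq_len(n_tuples), codes)
        gain <- sum(!covered[idx])
        if (gain > best_gain) {
          best_gain <- gain
          best_idx <- idx
          best_row <- cand[i, ]
        }
      }
      if (best_gain > 0L) {
        newly <- !covered[best_idx]
        covered[best_idx[newly, , drop = FALSE]] <- TRUE
        rows[[length(rows) + 1L]] <- best_row
      }
      # a zero-gain batch simply triggers a fresh candidate draw
    }
  })

  mat <- do.call(rbind, rows)
  dimnames(mat) <- NULL
  structure(
    list(matrix = mat, t = t, k = k, v = v, N = nrow(mat),
         method = "greedy-density", seed = seed),
    class = "covering_array"
  )
}

#' @export
print.covering_array <- function(x, ...) {
  cat(sprintf("<covering_array> CA(%d; %d, %d, %d), method=%s\n",
              x$N, x$t, x$k, x$v, x$method))
  invisible(x)
}

#' Verify the coverage property of a covering array
#'
#' Exhaustively checks that every selection of `t` columns contains all
#' `v^t` symbol tuples in at least one row. On failure the first
#' uncovered (columns, tuple) pair is returned as a witness.
#'
#' @param ca a `covering_array`, or a plain matrix together with `t`
#'   and `v`.
#' @param t,v strength and alphabet when `ca` is a plain matrix.
#' @return list with `covered` (logical) and, when not covered,
#'   `witness`: list with the offending `columns` and symbol `tuple`.
#' @export
verify_coverage <- function(ca, t = NULL, v = NULL) {
  if (inherits(ca, "covering_array")) {
    mat <- ca$matrix; t <- ca$t; v <- ca$v
  } else {
    mat <- as.matrix(ca)
    if (is.null(t) || is.null(v)) stop("supply t and v for a plain matrix",
                                       call. = FALSE)
  }
  if (nrow(mat) == 0) stop("matrix is empty", call. = FALSE)
  if (any(mat < 0) || any(mat >= v)) {
    stop("symbol outside {0..v-1}", call. = FALSE)
  }
  k <- ncol(mat)
  tuples <- .column_tuples(k, t)
  n_tuples <- nrow(tuples)
  covered <- matrix(FALSE, n_tuples, v^t)
  for (r in seq_len(nrow(mat))) {
    codes <- .tuple_codes(mat[r, ], tuples, v)
    covered[cbind(seq_len(n_tuples), codes)] <- TRUE
  }
  if (all(covered)) return(list(covered = TRUE, witness = NULL))
  miss <- which(!covered, arr.ind = TRUE)[1, ]
  code <- miss[2] - 1L
  tuple <- integer(t)
  for (j in t:1) {                # decode base-v, most significant first
    tuple[j] <- code %% v
    code <- code %/% v
  }
  list(covered = FALSE,
       witness = list(columns = tuples[miss[1], ], tuple = tuple))
}

#' Write a covering array as delimited text
#'
#' Three header lines (`N`, `t`, `k`, `v` on the first; method and seed
#' on the next two) followed by the matrix, space-delimited.
#'
#' @param ca a `covering_array`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_covering_array <- function(ca, path) {
  stopifnot(inherits(ca, "covering_array"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# N=%d t=%d k=%d v=%d", ca$N, ca$t, ca$k, ca$v),
               sprintf("# method=%s", ca$method),
               sprintf("# seed=%d", ca$seed)), con)
  utils::write.table(ca$matrix, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a covering array written by [write_covering_array()]
#'
#' @param path input file path.
#' @return a `covering_array`.
#' @export
read_covering_array <- function(path) {
  header <- readLines(path, n = 3)
  nums <- as.integer(regmatches(header[1],
                                gregexpr("[0-9]+", header[1]))[[1]])
  mat <- as.matrix(utils::read.table(path, skip = 3))
  dimnames(mat) <- NULL
  storage.mode(mat) <- "integer"
  structure(
    list(matrix = mat, t = nums[2], k = nums[3], v = nums[4], N = nums[1],
         method = sub("# method=", "", header[2], fixed = TRUE),
         seed = as.integer(sub("# seed=", "", header[3], fixed = TRUE))),
    class = "covering_array"
  )
}
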