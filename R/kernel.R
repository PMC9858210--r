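#' Construct and validate a Markov kernel
#'
#' A finite Markov kernel is a (possibly rectangular) matrix with non-negative
#' entries in which every row sums to 1. Rows index the conditioning states
#' (e.g. experiences), columns the target states (e.g. actions). A kernel is
#' *square* when its row and column labels coincide; only square kernels admit
#' chain analysis (communicating classes, invariant measures, flows).
#'
#' Rows whose sums deviate from 1 by no more than `tol_row` are renormalized
#' exactly to 1; larger deviations are rejected with an error naming the row.
#'
#' @param mat Numeric matrix (or object coercible to one) with finite,
#'   non-negative entries.
#' @param row_labels,col_labels Character vectors of state labels. Default to
#'   existing dimnames, else `"1"`, `"2"`, ... Row and column label sets are
#'   independent; equality of the two (in order) marks the kernel as square.
#' @param tol_row Absolute tolerance on each row sum (default `1e-9`).
#' @return An object of class `markov_kernel`: the validated matrix carrying
#'   its labels as dimnames.
#' @examples
#' # a kernel relating two states to three
#' kernel(rbind(c(.1, .3, .6), c(.4, .4, .2)))
#' # the two-state identity
#' kernel(diag(2))
#' @export
kernel <- function(mat, row_labels = NULL, col_labels = NULL, tol_row = 1e-9) {
  mat <- as.matrix(mat)
  if (length(mat) == 0L)
    stop("kernel matrix must be non-empty")
  storage.mode(mat) <- "double"
  if (any(!is.finite(mat)))
    stop("kernel matrix must have finite entries")
  if (is.null(row_labels)) row_labels <- rownames(mat)
  if (is.null(col_labels)) col_labels <- colnames(mat)
  if (is.null(row_labels)) row_labels <- as.character(seq_len(nrow(mat)))
  if (is.null(col_labels)) col_labels <- as.character(seq_len(ncol(mat)))
  row_labels <- as.character(row_labels)
  col_labels <- as.character(col_labels)
  if (length(row_labels) != nrow(mat) || length(col_labels) != ncol(mat))
    stop("label lengths do not match matrix dimensions")
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels))
    stop("state labels must be unique")

  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("negative entry %g at (%s, %s)",
                 mat[neg[1L, , drop = FALSE]],
                 row_labels[neg[1L, 1L]], col_labels[neg[1L, 2L]]))
  }
  rs <- rowSums(mat)
  bad <- which(abs(rs - 1) > tol_row)
  if (length(bad) > 0L) {
    stop(sprintf("row sum %g in row %s (must be 1 within %g)",
                 rs[bad[1L]], row_labels[bad[1L]], tol_row))
  }
  mat <- mat / rs  # renormalize dust within tolerance
  dimnames(mat) <- list(row_labels, col_labels)
  structure(mat, class = c("markov_kernel", "matrix", "array"))
}

#' @rdname kernel
#' @export
validate_kernel <- kernel

#' Test whether an object is a Markov kernel
#' @param x Object to test.
#' @export
is_kernel <- function(x) inherits(x, "markov_kernel")

#' @export
print.markov_kernel <- function(x, digits = 4, ...) {
  kind <- if (is_square(x)) "square" else "rectangular"
  cat(sprintf("Markov kernel (%d x %d, %s)\n", nrow(x), ncol(x), kind))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Is a kernel square (same row and column labels)?
#' @param Q A `markov_kernel`.
#' @export
is_square <- function(Q) {
  nrow(Q) == ncol(Q) && identical(rownames(Q), colnames(Q))
}

assert_square <- function(Q) {
  if (!is_kernel(Q)) Q <- kernel(Q)
  if (!is_square(Q))
    stop("a square kernel (identical row and column labels) is required")
  Q
}

#' Compose two kernels
#'
#' Composition of finite kernels is matrix multiplication: the `(a, c)` entry
#' of `compose(K1, K2)` is the probability of going from `a` to `c` through
#' all intermediate states of `K1`'s column space.
#'
#' @param K1,K2 Kernels with `colnames(K1) == rownames(K2)`.
#' @param tol_row Row-sum tolerance on the product.
#' @return The product kernel `K1 %*% K2`.
#' @export
compose <- function(K1, K2, tol_row = 1e-9) {
  if (!is_kernel(K1)) K1 <- kernel(K1)
  if (!is_kernel(K2)) K2 <- kernel(K2)
  if (!identical(colnames(K1), rownames(K2)))
    stop("shape mismatch: column labels of K1 must equal row labels of K2")
  kernel(unclass(K1) %*% unclass(K2),
         row_labels = rownames(K1), col_labels = colnames(K2),
         tol_row = tol_row)
}

#' Integer power of a square kernel
#'
#' @param Q Square kernel.
#' @param m Non-negative integer; `m = 0` gives the identity kernel on the
#'   states of `Q`.
#' @return The kernel `Q^m`.
#' @export
kernel_power <- function(Q, m) {
  Q <- assert_square(Q)
  if (length(m) != 1L || is.na(m) || m < 0 || m != round(m))
    stop("m must be a single non-negative integer")
  n <- nrow(Q)
  acc <- diag(n)
  base <- unclass(Q)
  m <- as.integer(m)
  while (m > 0L) {  # binary exponentiation
    if (m %% 2L == 1L) acc <- acc %*% base
    base <- base %*% base
    m <- m %/% 2L
  }
  kernel(acc, row_labels = rownames(Q), col_labels = colnames(Q))
}

#' Discrete kernel derivative
#'
#' The one-step difference `Q^2 - Q`, a generally non-Markovian matrix whose
#' rows sum to 0. Its off-diagonal entries give the local direction of the
#' kernel flow through the polytope of stochastic matrices; for a two-state
#' kernel parameterized by cross terms `(x, y)` they equal
#' `(x (1 - x - y), y (1 - x - y))`.
#'
#' @param Q Square kernel.
#' @return A plain numeric matrix (not a kernel) with zero row sums.
#' @export
kernel_derivative <- function(Q) {
  Q <- assert_square(Q)
  m <- unclass(Q)
  m %*% m - m
}

#' Idempotence test
#'
#' A kernel is stationary when it is idempotent, `Q Q = Q`. Idempotent
#' row-stochastic matrices whose rows are all equal have rank one and sit on
#' the fusion simplex.
#'
#' @param Q Square kernel.
#' @param tol Entrywise tolerance on `Q^2 - Q` (default `1e-9`).
#' @export
is_idempotent <- function(Q, tol = 1e-9) {
  Q <- assert_square(Q)
  max(abs(kernel_derivative(Q))) <= tol
}

#' Two-state kernel from its cross terms
#'
#' The polytope of two-state kernels is the unit square with coordinates
#' `x = p(2 | 1)` and `y = p(1 | 2)`; the kernel is
#' `rbind(c(1 - x, x), c(y, 1 - y))`. `(0, 0)` is the identity, `(1, 1)` the
#' NOT (bit-flip) kernel, and the anti-diagonal `x + y = 1` is the line of
#' rank-one stationary kernels.
#'
#' @param x,y Cross-term probabilities in `[0, 1]`.
#' @param labels Two state labels.
#' @return A 2 x 2 `markov_kernel`.
#' @export
m2_kernel <- function(x, y, labels = c("1", "2")) {
  if (x < 0 || x > 1 || y < 0 || y > 1)
    stop("cross terms must lie in [0, 1]")
  kernel(rbind(c(1 - x, x), c(y, 1 - y)),
         row_labels = labels, col_labels = labels)
}
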