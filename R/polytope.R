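#' Dimension and vertex count of the Markov polytope
#'
#' The Markov polytope `Mn` is the set of all `n x n` row-stochastic
#' matrices: a product of `n` probability simplices, hence an
#' `n(n-1)`-dimensional polytope with `n^n` vertices (the deterministic 0/1
#' kernels).
#'
#' @param n Number of states, `n >= 1`.
#' @return List with `dimension` and `vertex_count`.
#' @examples
#' polytope_summary(2)  # dimension 2, 4 vertices: the unit square
#' polytope_summary(3)  # dimension 6, 27 vertices
#' @export
polytope_summary <- function(n) {
  n <- check_n(n)
  list(dimension = n * (n - 1L), vertex_count = n^n)
}

check_n <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("n must be a single integer >= 1")
  as.integer(n)
}

#' Vertices of the Markov polytope
#'
#' Enumerates all `n^n` deterministic kernels (exactly one 1 per row) in
#' row-major function order: the image of state 1 varies slowest.
#'
#' @param n Number of states; guarded at `n <= 6` (`6^6 = 46656` kernels).
#' @return List of `markov_kernel` objects.
#' @export
polytope_vertices <- function(n) {
  n <- check_n(n)
  if (n > 6L) stop("n > 6 would enumerate more than 6^6 vertices; refusing")
  lapply(seq_len(n^n) - 1L, function(code) {
    deterministic_kernel(vertex_map(code, n), n)
  })
}

# digits of `code` base n, most significant first, as images in 1..n
vertex_map <- function(code, n) {
  img <- integer(n)
  for (i in n:1) {
    img[i] <- (code %% n) + 1L
    code <- code %/% n
  }
  img
}

#' Deterministic kernel from a transition map
#'
#' @param images Integer vector: state `i` moves to `images[i]` with
#'   probability 1.
#' @param n Number of states (defaults to `length(images)`).
#' @return A `markov_kernel`.
#' @export
deterministic_kernel <- function(images, n = length(images)) {
  m <- matrix(0, n, n)
  m[cbind(seq_len(n), as.integer(images))] <- 1
  kernel(m)
}

#' Vertex adjacency graph of the Markov polytope
#'
#' Two deterministic kernels are adjacent on `Mn` (joined by an edge of the
#' product-of-simplices polytope) iff they differ in exactly one row. The
#' graph is regular of degree `n(n-1)`.
#'
#' @param n Number of states; guarded at `n <= 5`.
#' @return An undirected `igraph` graph on `n^n` vertices, numbered in the
#'   order of [polytope_vertices()].
#' @export
vertex_adjacency <- function(n) {
  n <- check_n(n)
  if (n > 5L) stop("n > 5 would build a graph on more than 5^5 vertices; refusing")
  nv <- n^n
  maps <- t(vapply(seq_len(nv) - 1L, vertex_map, integer(n), n = n))
  from <- integer(); to <- integer()
  for (i in seq_len(nv - 1L)) {
    for (j in (i + 1L):nv) {
      if (sum(maps[i, ] != maps[j, ]) == 1L) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
}

#' Cell label of a kernel in the Markov polytope
#'
#' The polytope `Mn` is a cell complex: the cell of a kernel is the set of
#' kernels sharing its decorated permutation, which depends only on the
#' support pattern. Delegates to [dperm_from_markov()].
#'
#' @param Q Square kernel.
#' @param tol_zero Structural-zero tolerance.
#' @return A `decorated_perm`.
#' @export
cell_of <- function(Q, tol_zero = 0) dperm_from_markov(Q, tol_zero = tol_zero)

#' Census of support-pattern cells of the Markov polytope
#'
#' Enumerates every row-support pattern (each row an arbitrary non-empty
#' subset of the states, `(2^n - 1)^n` patterns in all), labels each by the
#' decorated permutation of a representative kernel with uniform positive
#' entries on the support, and tallies patterns per cell.
#'
#' @param n Number of states; guarded at `n <= 3` (`343` patterns).
#' @return Named integer vector: bracket-string cell label -> number of
#'   support patterns in the cell, sorted by label.
#' @examples
#' enumerate_support_cells(2)  # the four cells of the unit square
#' @export
enumerate_support_cells <- function(n) {
  n <- check_n(n)
  if (n > 3L) stop("n > 3 would enumerate more than 7^3 support patterns; refusing")
  subsets <- lapply(seq_len(2^n - 1L), function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
  })
  counts <- integer()
  idx <- rep(1L, n)
  repeat {
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      s <- subsets[[idx[i]]]
      m[i, s] <- 1 / length(s)
    }
    lab <- format_sigma(dperm_from_markov(kernel(m)))
    counts[lab] <- if (is.na(counts[lab])) 1L else counts[lab] + 1L
    # odometer over the n independent row subsets
    pos <- 1L
    while (pos <= n) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= length(subsets)) break
      idx[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > n) break
  }
  counts[order(names(counts))]
}

#' Points of the fusion simplex
#'
#' A fusion point is a probability vector over `n` qualia labels: the mixture
#' weights of the single new quale created when `n` agents fuse. The fusion
#' simplex `Fn` is the unit `(n-1)`-simplex of all such points.
#'
#' @param weights Non-negative numeric vector summing to 1 (within `1e-12`),
#'   optionally named by quale label.
#' @return An object of class `fusion_point`.
#' @export
fusion_point <- function(weights) {
  w <- as.numeric(weights)
  if (any(w < 0)) stop("fusion weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-12)
    stop(sprintf("fusion weights must sum to 1 (got %.15g)", sum(w)))
  labels <- names(weights)
  if (is.null(labels)) labels <- as.character(seq_along(w))
  structure(stats::setNames(w, labels), class = "fusion_point")
}

#' @export
print.fusion_point <- function(x, ...) {
  cat("fusion point (", paste(signif(unclass(x), 6), collapse = ", "), ")\n")
  invisible(x)
}

#' Rank-one stationary kernel of a fusion point
#'
#' The fusion kernel of weights `mu` is the `n x n` kernel with every row
#' equal to `mu`: idempotent, rank one, and with unique invariant measure
#' `mu`. These kernels form the fusion simplex inside the Markov polytope.
#'
#' @param weights A `fusion_point` (or a probability vector).
#' @return A `markov_kernel`.
#' @export
fusion_kernel <- function(weights) {
  if (!inherits(weights, "fusion_point")) weights <- fusion_point(weights)
  n <- length(weights)
  kernel(matrix(unclass(weights), n, n, byrow = TRUE),
         row_labels = names(weights), col_labels = names(weights))
}

#' Extract the fusion point of a fused kernel
#'
#' A kernel signals fusion when it has dropped to a rank-one idempotent: all
#' rows equal. `fuse()` verifies idempotence and the rank drop, and returns
#' the common row as the mixture weights of the new single quale.
#'
#' @param Q Square kernel.
#' @param tol Tolerance for the idempotence and equal-rows tests.
#' @return A `fusion_point`.
#' @export
fuse <- function(Q, tol = 1e-9) {
  Q <- assert_square(Q)
  if (!is_idempotent(Q, tol = tol))
    stop("not fused: kernel is not idempotent")
  m <- unclass(Q)
  spread <- max(apply(m, 2, function(col) diff(range(col))))
  if (spread > tol)
    stop(sprintf("not fused: kernel has rank > 1 (rows differ by %g)", spread))
  w <- colMeans(m)
  fusion_point(stats::setNames(w / sum(w), colnames(Q)))
}

#' Slope of an invariant-measure line in the two-state polytope
#'
#' All two-state kernels with invariant measure `(alpha, 1 - alpha)` lie on
#' the line `y = alpha / (1 - alpha) * x` through the origin of the unit
#' square `(x, y)`; this returns that slope.
#'
#' @param alpha Weight of the first state, strictly between 0 and 1.
#' @export
invariant_line_slope <- function(alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  alpha / (1 - alpha)
}

#' Kernel flow field on the two-state polytope
#'
#' Evaluates the discrete kernel derivative on a regular grid over the unit
#' square: at `(x, y)` the flow direction is
#' `(dx, dy) = (x (1 - x - y), y (1 - x - y))`. The identity corner `(0, 0)`
#' is the unique source; the fusion line `x + y = 1` is the line of sinks;
#' the NOT corner `(1, 1)` is periodic and does not flow.
#'
#' @param grid_resolution Number of grid points per side, at least 2.
#' @return A data frame of class `flow_field_m2` with columns `x, y, dx, dy`.
#' @export
flow_field_m2 <- function(grid_resolution = 11) {
  if (grid_resolution < 2) stop("grid_resolution must be at least 2")
  s <- seq(0, 1, length.out = grid_resolution)
  g <- expand.grid(x = s, y = s, KEEP.OUT.ATTRS = FALSE)
  g$dx <- g$x * (1 - g$x - g$y)
  g$dy <- g$y * (1 - g$x - g$y)
  class(g) <- c("flow_field_m2", "data.frame")
  g
}

#' Mix palette colors by fusion weights
#'
#' The quale created by a fusion is depicted as the convex combination of the
#' original qualia's colors with the fusion-point weights.
#'
#' @param weights A `fusion_point` (or probability vector) named by quale
#'   label, or unnamed with labels taken positionally from the palette.
#' @param palette Matrix with one RGB row (values in `[0, 1]`) per quale,
#'   rownames = quale labels, or a named list of length-3 vectors.
#' @return Numeric RGB triple in `[0, 1]`.
#' @examples
#' pal <- rbind(red = c(1, 0, 0), green = c(0, 1, 0))
#' qualia_mix(fusion_point(c(red = .5, green = .5)), pal)
#' @export
qualia_mix <- function(weights, palette) {
  if (!inherits(weights, "fusion_point")) weights <- fusion_point(weights)
  if (is.list(palette)) palette <- do.call(rbind, palette)
  palette <- as.matrix(palette)
  if (ncol(palette) != 3L) stop("palette must have three (RGB) columns")
  labs <- names(weights)
  if (is.null(rownames(palette))) {
    if (nrow(palette) < length(weights))
      stop("palette does not cover all qualia labels")
    rows <- seq_along(weights)
  } else {
    rows <- match(labs, rownames(palette))
    if (anyNA(rows))
      stop(sprintf("palette has no entry for quale %s",
                   dQuote(labs[which(is.na(rows))[1L]])))
  }
  as.numeric(unclass(weights) %*% palette[rows, , drop = FALSE])
}
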