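#' Decorated permutations
#'
#' A decorated permutation on `n` elements is an injective map
#' `sigma: {1..n} -> {1..2n}` with `a <= sigma(a) <= a + n` whose mod-`n`
#' reduction (residues taken in `{1..n}`) is an ordinary permutation. A fixed
#' point of the underlying permutation carries a binary decoration: it maps
#' either to `a` (undecorated, "white") or to `a + n` (decorated, "black").
#' Decorated permutations label the cells of the positive Grassmannian and,
#' here, the cells of the polytope of stochastic matrices.
#'
#' @param images Integer vector of length `n`, the values `sigma(1..n)`.
#' @param n Ground-set size; defaults to `length(images)`.
#' @return An object of class `decorated_perm` with fields `n` and `images`.
#' @examples
#' decorated_perm(c(3, 4, 5, 6))
#' decorated_perm(c(8, 11, 4, 12, 10, 15, 9, 14, 16))
#' @export
decorated_perm <- function(images, n = length(images)) {
  images <- as.integer(images)
  if (length(images) != n)
    stop(sprintf("expected %d images, got %d", n, length(images)))
  a <- seq_len(n)
  bad <- which(images < a | images > a + n)
  if (length(bad) > 0L)
    stop(sprintf(
      "range violation: sigma(%d) = %d outside [%d, %d] (need a <= sigma(a) <= a + n)",
      bad[1L], images[bad[1L]], bad[1L], bad[1L] + n))
  res <- mod1(images, n)
  if (anyDuplicated(res))
    stop(sprintf(
      "mod-%d collision at residue %d: sigma mod n must be a bijection",
      n, res[anyDuplicated(res)]))
  structure(list(n = n, images = images), class = "decorated_perm")
}

# residues in {1..n}
mod1 <- function(v, n) ((v - 1L) %% n) + 1L

#' @export
print.decorated_perm <- function(x, ...) {
  cat("decorated permutation", format_sigma(x), "\n")
  invisible(x)
}

#' @export
format.decorated_perm <- function(x, ...) format_sigma(x)

#' @export
`==.decorated_perm` <- function(e1, e2) {
  e1$n == e2$n && all(e1$images == e2$images)
}

#' Bracket-string serialization of decorated permutations
#'
#' `format_sigma()` renders a decorated permutation as the 1-based bracket
#' string `"[8,11,4,12,10,15,9,14,16]"`; `parse_sigma()` inverts it,
#' validating the result.
#'
#' @param sigma A `decorated_perm`.
#' @param text A bracket string.
#' @return A character scalar, resp. a `decorated_perm`.
#' @export
format_sigma <- function(sigma) {
  stopifnot(inherits(sigma, "decorated_perm"))
  paste0("[", paste(sigma$images, collapse = ","), "]")
}

#' @rdname format_sigma
#' @export
parse_sigma <- function(text) {
  text <- trimws(text)
  if (!grepl("^\\[[0-9]+(,[0-9]+)*\\]$", text))
    stop(sprintf("cannot parse decorated permutation from %s", dQuote(text)))
  vals <- as.integer(strsplit(substr(text, 2L, nchar(text) - 1L), ",")[[1L]])
  decorated_perm(vals)
}

#' Underlying ordinary permutation
#'
#' The mod-`n` reduction of a decorated permutation, with residues in
#' `{1..n}`, as a plain integer permutation vector.
#'
#' @param sigma A `decorated_perm`.
#' @export
underlying_perm <- function(sigma) {
  stopifnot(inherits(sigma, "decorated_perm"))
  mod1(sigma$images, sigma$n)
}

#' All decorations of an ordinary permutation
#'
#' Non-fixed points are forced (`s(a)` if `s(a) > a`, `s(a) + n` if
#' `s(a) < a`); each of the `k` fixed points independently maps to `a` or
#' `a + n`, giving `2^k` decorated permutations.
#'
#' @param s Integer permutation vector on `{1..n}`.
#' @return List of `decorated_perm` objects, in binary-counter order over the
#'   fixed points (undecorated first).
#' @export
decorations_of <- function(s) {
  s <- as.integer(s)
  n <- length(s)
  if (!identical(sort(s), seq_len(n)))
    stop("s must be a permutation of 1..n")
  a <- seq_len(n)
  base <- ifelse(s > a, s, ifelse(s < a, s + n, s))
  fixed <- which(s == a)
  k <- length(fixed)
  if (k == 0L) return(list(decorated_perm(base)))
  lapply(seq_len(2^k) - 1L, function(code) {
    img <- base
    up <- fixed[bitwAnd(bitwShiftR(code, seq_len(k) - 1L), 1L) == 1L]
    img[up] <- img[up] + n
    decorated_perm(img)
  })
}

#' Is a decorated permutation a decoration of the identity?
#' @param sigma A `decorated_perm`.
#' @export
is_identity_decoration <- function(sigma) {
  a <- seq_len(sigma$n)
  all(sigma$images == a | sigma$images == a + sigma$n)
}

# Shared window rule. For a state `a` whose class (set of residues in
# {1..n}) is `cl`, sigma(a) is the smallest b > a such that b reduces to a
# class member and the inclusive run a, a+1, ..., b — read as residues mod n
# — covers the whole class. The literal "first b whose window contains the
# class" clause alone would give b = a + 1 for an absorbing singleton; the
# extra requirement that b itself reduce into the class makes the rule return
# a + n there, consistently with the absorbing convention, and reproduces the
# nine-state worked example as well as the corner cells of the two-state
# polytope.
window_image <- function(a, cl, n) {
  for (b in (a + 1L):(a + n)) {
    if (!(mod1(b, n) %in% cl)) next
    window <- mod1(a:b, n)
    if (all(cl %in% window)) return(b)
  }
  stop(sprintf("window rule failed for state %d", a))  # unreachable for valid classes
}

#' Decorated permutation of a Markov chain
#'
#' Projects a square kernel to a decorated permutation from its communicating
#' classes: a transient state maps to itself (`sigma(a) = a`); a recurrent
#' state `a` maps to the first `b > a` in `{1..2n}` that reduces mod `n` into
#' the class of `a` and whose inclusive run `a..b` (as residues) covers that
#' class. An absorbing state consequently maps to `a + n`. The result depends
#' only on the support pattern of the kernel.
#'
#' @param Q Square kernel.
#' @param tol_zero Structural-zero tolerance for the support digraph.
#' @return A `decorated_perm`.
#' @examples
#' dperm_from_markov(kernel(diag(2)))   # [3,4]
#' dperm_from_markov(m2_kernel(1, 1))   # [2,3], the NOT kernel
#' @export
dperm_from_markov <- function(Q, tol_zero = 0) {
  Q <- assert_square(Q)
  cs <- communicating_classes(Q, tol_zero = tol_zero)
  n <- nrow(Q)
  images <- integer(n)
  for (i in seq_along(cs$classes)) {
    cl <- cs$classes[[i]]
    for (a in cl) {
      images[a] <- if (cs$recurrent[i]) window_image(a, cl, n) else a
    }
  }
  decorated_perm(images, n)
}

#' Decorated permutation of a directed graph
#'
#' Generalization of [dperm_from_markov()] to arbitrary digraphs on nodes
#' `{1..n}`: an isolated node maps to itself; a node whose only edge is its
#' self-loop maps to `a + n`; a singleton strongly connected component with
#' edges to or from other nodes is treated like a transient state
#' (`sigma(a) = a`); any other node follows the window rule applied to its
#' strongly connected component. On the support digraph of a kernel whose
#' non-singleton components are all recurrent this agrees with
#' [dperm_from_markov()].
#'
#' @param edges Two-column integer matrix (or data frame) of directed edges
#'   `src -> dst`, or an `igraph` graph.
#' @param n Number of nodes; defaults to the largest endpoint (or the graph's
#'   vertex count).
#' @return A `decorated_perm`.
#' @export
dperm_from_graph <- function(edges, n = NULL) {
  if (inherits(edges, "igraph")) {
    g <- edges
    if (is.null(n)) n <- igraph::vcount(g)
    em <- igraph::as_edgelist(g, names = FALSE)
  } else {
    em <- as.matrix(edges)
    if (length(em) == 0L) em <- matrix(integer(), 0L, 2L)
    storage.mode(em) <- "integer"
    if (ncol(em) != 2L) stop("edges must have two columns (src, dst)")
    if (is.null(n)) n <- if (nrow(em) == 0L) 0L else max(em)
    g <- igraph::graph_from_edgelist(em, directed = TRUE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  }
  if (n < 1L) stop("graph must have at least one node")
  memb <- igraph::components(g, mode = "strong")$membership
  has_self <- rep(FALSE, n)
  other <- rep(FALSE, n)   # any edge to or from a different node
  outgoing <- rep(FALSE, n)
  if (nrow(em) > 0L) {
    self <- em[, 1L] == em[, 2L]
    has_self[unique(em[self, 1L])] <- TRUE
    other[unique(c(em[!self, 1L], em[!self, 2L]))] <- TRUE
    outgoing[unique(em[!self, 1L])] <- TRUE
  }
  images <- integer(n)
  for (a in seq_len(n)) {
    cl <- which(memb == memb[a])
    if (length(cl) > 1L) {
      images[a] <- window_image(a, cl, n)
    } else if (!has_self[a] && !other[a]) {
      images[a] <- a                     # no links at all
    } else if (has_self[a] && !outgoing[a]) {
      images[a] <- a + n                 # only (out-)links with itself
    } else {
      images[a] <- a                     # transient-like singleton
    }
  }
  decorated_perm(images, n)
}

#' Decorated permutation of a full-rank matrix (Grassmannian labeling)
#'
#' A full-rank `k x n` matrix `C` represents a `k`-plane in `n`-space. Repeat
#' its `n` columns in order to a `k x 2n` matrix; the decorated permutation
#' assigns to each column `a` the first column `b > a` of the expanded matrix
#' such that column `a` lies in the span of columns `a+1, ..., b`. A zero
#' column maps to itself. Span membership is decided by rank comparison.
#'
#' @param C Numeric `k x n` matrix of full row rank `k`.
#' @param tol Relative tolerance for the rank computations (default `1e-9`).
#' @return A `decorated_perm` on `n` elements.
#' @export
dperm_from_grassmannian <- function(C, tol = 1e-9) {
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  k <- nrow(C); n <- ncol(C)
  if (mat_rank(C, tol) < k)
    stop(sprintf("C must have full row rank %d", k))
  images <- integer(n)
  scale <- max(abs(C))
  for (a in seq_len(n)) {
    ca <- C[, a, drop = FALSE]
    if (all(abs(ca) <= tol * scale)) {
      images[a] <- a
      next
    }
    for (b in (a + 1L):(a + n)) {
      S <- C[, mod1((a + 1L):b, n), drop = FALSE]
      if (mat_rank(cbind(S, ca), tol) == mat_rank(S, tol)) {
        images[a] <- b
        break
      }
    }
  }
  decorated_perm(images, n)
}

mat_rank <- function(M, tol = 1e-9) {
  if (length(M) == 0L || all(M == 0)) return(0L)
  qr(M, tol = tol)$rank
}
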