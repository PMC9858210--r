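#' Communicating classes of a square kernel
#'
#' States `a` and `b` communicate when each is reachable from the other with
#' positive probability in finitely many steps. Mutual communication is an
#' equivalence relation; its classes partition the state space. A class is
#' *recurrent* when no support edge leaves it, *transient* otherwise; an
#' *absorbing* state is a recurrent singleton with self-probability 1. The
#' period of a class with at least one internal cycle is the gcd of its
#' support-cycle lengths.
#'
#' Entries no larger than `tol_zero` are treated as structural zeros when
#' building the support digraph; the default keeps only exact zeros out, but a
#' positive value is useful when renormalization has produced numerical dust.
#'
#' @param Q Square kernel.
#' @param tol_zero Entries `<= tol_zero` are treated as zero (default 0).
#' @return An object of class `class_structure`: a list with components
#'   `classes` (list of integer state-index vectors, ordered by smallest
#'   member), `labels` (per-class state labels), `recurrent`, `absorbing`
#'   (logical per class), and `period` (integer per class; `NA` for an acyclic
#'   transient singleton).
#' @examples
#' # two absorbing singletons
#' communicating_classes(kernel(diag(2)))
#' @export
communicating_classes <- function(Q, tol_zero = 0) {
  Q <- assert_square(Q)
  n <- nrow(Q)
  supp <- unclass(Q) > tol_zero
  g <- igraph::graph_from_adjacency_matrix(supp * 1, mode = "directed")
  memb <- igraph::components(g, mode = "strong")$membership

  # classes ordered by smallest state index
  cls <- split(seq_len(n), memb)
  cls <- cls[order(vapply(cls, min, 1L))]
  names(cls) <- NULL

  recurrent <- vapply(cls, function(cl) {
    !any(supp[cl, -cl, drop = FALSE] & TRUE) || length(cl) == n
  }, logical(1))
  absorbing <- vapply(seq_along(cls), function(i) {
    cl <- cls[[i]]
    recurrent[i] && length(cl) == 1L && abs(Q[cl, cl] - 1) <= tol_zero + 1e-12
  }, logical(1))
  period <- vapply(cls, function(cl) class_period(supp, cl), integer(1))

  structure(list(
    classes = cls,
    labels = lapply(cls, function(cl) rownames(Q)[cl]),
    recurrent = recurrent,
    absorbing = absorbing,
    period = period
  ), class = "class_structure")
}

# gcd of cycle lengths within a strongly connected class, via BFS levels:
# for each internal edge u -> v, level(u) + 1 - level(v) is a multiple of the
# period, and their gcd attains it. NA when the class has no internal edge.
class_period <- function(supp, cl) {
  sub <- supp[cl, cl, drop = FALSE]
  if (!any(sub)) return(NA_integer_)
  k <- length(cl)
  level <- rep(NA_integer_, k)
  level[1L] <- 0L
  queue <- 1L
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in which(sub[u, ])) {
      if (is.na(level[v])) {
        level[v] <- level[u] + 1L
        queue <- c(queue, v)
      }
    }
  }
  g <- 0L
  for (u in seq_len(k)) {
    for (v in which(sub[u, ])) {
      d <- level[u] + 1L - level[v]
      g <- gcd_int(g, abs(d))
    }
  }
  if (g == 0L) NA_integer_ else g
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- a %% b; a <- b; b <- t }
  as.integer(a)
}

#' @export
print.class_structure <- function(x, ...) {
  cat(sprintf("%d communicating class(es)\n", length(x$classes)))
  for (i in seq_along(x$classes)) {
    flag <- if (x$absorbing[i]) "absorbing"
            else if (x$recurrent[i]) "recurrent" else "transient"
    per <- if (is.na(x$period[i])) "" else sprintf(", period %d", x$period[i])
    cat(sprintf("  {%s}: %s%s\n", paste(x$labels[[i]], collapse = ","),
                flag, per))
  }
  invisible(x)
}

#' Extremal invariant measures of a square kernel
#'
#' A probability vector `mu` is invariant for `Q` when `mu Q = mu`. The
#' extreme points of the set of invariant measures are in bijection with the
#' recurrent classes: each extremal measure is the unique stationary
#' distribution of one recurrent class, supported on that class. Any invariant
#' measure is a convex combination of these.
#'
#' @param Q Square kernel.
#' @param tol_zero Structural-zero tolerance passed to
#'   [communicating_classes()].
#' @return A list of numeric probability vectors over all states (named by
#'   state label), one per recurrent class, in class order (classes sorted by
#'   smallest state index). A single element iff the recurrent class is
#'   unique.
#' @examples
#' invariant_measures(m2_kernel(0.5, 0.25))[[1]]  # (1/3, 2/3)
#' @export
invariant_measures <- function(Q, tol_zero = 0) {
  Q <- assert_square(Q)
  cs <- communicating_classes(Q, tol_zero = tol_zero)
  n <- nrow(Q)
  out <- list()
  for (i in seq_along(cs$classes)) {
    if (!cs$recurrent[i]) next
    cl <- cs$classes[[i]]
    mu <- rep(0, n)
    mu[cl] <- class_stationary(unclass(Q)[cl, cl, drop = FALSE])
    names(mu) <- rownames(Q)
    out[[length(out) + 1L]] <- mu
  }
  out
}

# stationary distribution of an irreducible stochastic matrix P (rows of a
# recurrent class): solve mu (P - I) = 0 with the normalization sum(mu) = 1
# replacing one redundant equation.
class_stationary <- function(P) {
  k <- nrow(P)
  if (k == 1L) return(1)
  A <- t(P) - diag(k)
  A[k, ] <- 1
  b <- c(rep(0, k - 1L), 1)
  mu <- solve(A, b)
  mu[mu < 0 & mu > -1e-12] <- 0  # clip solver dust
  mu / sum(mu)
}

#' Long-run flow of a square kernel
#'
#' The flow of a kernel `Q` is the limit of its powers, `lim Q^m`, when it
#' exists, i.e. when every recurrent class is aperiodic. The limit is computed
#' exactly from the class structure rather than by iterating powers: each
#' recurrent state's row is its class's stationary distribution, and each
#' transient state's row mixes the recurrent stationary distributions with the
#' absorption probabilities into each recurrent class (solved from the linear
#' system on the transient block). With `mode = "cesaro"` the Cesaro average
#' `lim (1/N) sum Q^m` is returned instead; it always exists and is given by
#' the same algebraic formula irrespective of periodicity.
#'
#' The flow, when defined, is an idempotent kernel; its rows are convex
#' combinations of the extremal invariant measures.
#'
#' @param Q Square kernel.
#' @param mode `"power"` (default) or `"cesaro"`.
#' @param tol_zero Structural-zero tolerance.
#' @return A `markov_kernel` (the limit), or — for `mode = "power"` when some
#'   recurrent class is periodic — a `flow_periodicity_report` naming the
#'   periodic classes and their periods.
#' @examples
#' kernel_flow(m2_kernel(0.5, 0.25))        # both rows (1/3, 2/3)
#' kernel_flow(m2_kernel(1, 1))             # periodicity report (NOT kernel)
#' kernel_flow(m2_kernel(1, 1), "cesaro")   # rows (1/2, 1/2)
#' @export
kernel_flow <- function(Q, mode = c("power", "cesaro"), tol_zero = 0) {
  Q <- assert_square(Q)
  mode <- match.arg(mode)
  cs <- communicating_classes(Q, tol_zero = tol_zero)
  rec <- which(cs$recurrent)

  if (mode == "power") {
    periodic <- rec[cs$period[rec] > 1L]
    if (length(periodic) > 0L) {
      return(structure(list(
        classes = cs$labels[periodic],
        period = cs$period[periodic]
      ), class = "flow_periodicity_report"))
    }
  }

  n <- nrow(Q)
  L <- matrix(0, n, n)
  stat <- vector("list", length(cs$classes))
  for (i in rec) {
    cl <- cs$classes[[i]]
    stat[[i]] <- class_stationary(unclass(Q)[cl, cl, drop = FALSE])
    for (a in cl) L[a, cl] <- stat[[i]]
  }
  trans <- unlist(cs$classes[!cs$recurrent], use.names = FALSE)
  if (length(trans) > 0L) {
    # absorption probabilities: h = (I - Q_TT)^{-1} Q_TC 1 per recurrent class
    QTT <- unclass(Q)[trans, trans, drop = FALSE]
    M <- diag(length(trans)) - QTT
    for (i in rec) {
      cl <- cs$classes[[i]]
      rhs <- rowSums(unclass(Q)[trans, cl, drop = FALSE])
      h <- solve(M, rhs)
      L[trans, cs$classes[[i]]] <- L[trans, cl, drop = FALSE] +
        outer(h, stat[[i]])
    }
  }
  kernel(L, row_labels = rownames(Q), col_labels = colnames(Q))
}

#' @export
print.flow_periodicity_report <- function(x, ...) {
  cat("power limit does not exist: periodic recurrent class(es)\n")
  for (i in seq_along(x$classes)) {
    cat(sprintf("  {%s}: period %d\n",
                paste(x$classes[[i]], collapse = ","), x$period[i]))
  }
  invisible(x)
}
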