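#' Construct a conscious agent
#'
#' An agent is a 6-tuple of three finite label sets — experiences `X`, actions
#' `G`, world states `W` — and three Markov kernels linking them in a cycle:
#' a decision kernel `D: X -> G` (which action follows an experience), an
#' action kernel `A: G -> W` (how an action moves the world), and a perception
#' kernel `P: W -> X` (which experience the world induces). The label sets are
#' read off the kernels; the three kernels must chain shape-compatibly.
#'
#' @param P Perception kernel, rows `W`, columns `X`.
#' @param D Decision kernel, rows `X`, columns `G`.
#' @param A Action kernel, rows `G`, columns `W`.
#' @return An object of class `conscious_agent` with components `X`, `G`, `W`
#'   (character label vectors) and `P`, `D`, `A`.
#' @export
make_agent <- function(P, D, A) {
  if (!is_kernel(P)) P <- kernel(P)
  if (!is_kernel(D)) D <- kernel(D)
  if (!is_kernel(A)) A <- kernel(A)
  if (!identical(colnames(D), rownames(A)))
    stop("shape mismatch between D and A: colnames(D) must equal rownames(A)")
  if (!identical(colnames(A), rownames(P)))
    stop("shape mismatch between A and P: colnames(A) must equal rownames(P)")
  if (!identical(colnames(P), rownames(D)))
    stop("shape mismatch between P and D: colnames(P) must equal rownames(D)")
  structure(list(
    X = rownames(D), G = colnames(D), W = colnames(A),
    P = P, D = D, A = A
  ), class = "conscious_agent")
}

#' @export
print.conscious_agent <- function(x, ...) {
  cat(sprintf("conscious agent: |X| = %d, |G| = %d, |W| = %d\n",
              length(x$X), length(x$G), length(x$W)))
  invisible(x)
}

#' Qualia kernel of an agent
#'
#' The qualia kernel `Q = D A P` composes decision, action, and perception
#' into a square kernel on the experience set `X`: the agent's sequential
#' experiencing, with its internal mechanism and its world marginalized out.
#' A 1-agent (a single experience) has the Dirac kernel `[1]`.
#'
#' @param agent A `conscious_agent`.
#' @return A square `markov_kernel` on `X`.
#' @export
qualia_kernel <- function(agent) {
  stopifnot(inherits(agent, "conscious_agent"))
  compose(compose(agent$D, agent$A), agent$P)
}

#' Combine two agents into a product agent
#'
#' The product agent lives on the cartesian products of the experience,
#' action, and world sets, with tensor (Kronecker) product kernels. Product
#' labels are ordered lexicographically with the first agent major, pasted
#' with `":"`, so the qualia kernel of the product is exactly the Kronecker
#' product `Q1 %x% Q2` of the factors' qualia kernels (mixed-product
#' property). The cross terms between the factors' qualia are zero: the
#' combined agent is block-diagonal, i.e. non-interacting.
#'
#' @param a1,a2 `conscious_agent` objects.
#' @return A `conscious_agent` on the product sets.
#' @export
combine_product <- function(a1, a2) {
  stopifnot(inherits(a1, "conscious_agent"), inherits(a2, "conscious_agent"))
  kron <- function(K1, K2) {
    m <- kronecker(unclass(K1), unclass(K2))
    kernel(m,
           row_labels = cross_labels(rownames(K1), rownames(K2)),
           col_labels = cross_labels(colnames(K1), colnames(K2)))
  }
  make_agent(P = kron(a1$P, a2$P), D = kron(a1$D, a2$D), A = kron(a1$A, a2$A))
}

cross_labels <- function(l1, l2) {
  as.vector(t(outer(l1, l2, paste, sep = ":")))
}

#' Joint qualia kernel of 1-agents with arbitrary cross terms
#'
#' `n` 1-agents, each carrying a single quale, can combine on the union of
#' their qualia with arbitrary interaction cross terms, provided the cross
#' terms form a row-stochastic matrix. For `n = 2` the kernel is the familiar
#' two-parameter family `m2_kernel(x, y)` with `x = p(2 | 1)`,
#' `y = p(1 | 2)`; zero cross terms give the identity (non-interacting
#' agents).
#'
#' @param qualia_labels Character vector of `n` quale labels.
#' @param cross An `n x n` row-stochastic matrix of conditional probabilities
#'   between qualia.
#' @param tol_row Row-sum tolerance.
#' @return A square `markov_kernel` on the qualia labels.
#' @export
combine_union <- function(qualia_labels, cross, tol_row = 1e-9) {
  qualia_labels <- as.character(qualia_labels)
  cross <- as.matrix(cross)
  if (nrow(cross) != length(qualia_labels) ||
      ncol(cross) != length(qualia_labels))
    stop("cross must be n x n for n qualia labels")
  kernel(cross, row_labels = qualia_labels, col_labels = qualia_labels,
         tol_row = tol_row)
}

#' Realize a kernel as some agent's qualia kernel
#'
#' Constructive witness that every square Markov kernel on a label set is the
#' qualia kernel of some agent: take `X = G = W` equal to the states, the
#' decision kernel `D = Q`, and identity action and perception kernels. Then
#' `D A P = Q` exactly.
#'
#' @param Q Square kernel.
#' @return A `conscious_agent` whose [qualia_kernel()] is `Q`.
#' @export
realize_agent <- function(Q) {
  Q <- assert_square(Q)
  id <- kernel(diag(nrow(Q)), row_labels = rownames(Q),
               col_labels = colnames(Q))
  make_agent(P = id, D = Q, A = id)
}
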