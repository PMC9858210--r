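---
title: "Markov kernels, fusion, and decorated permutations: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov kernels, fusion, and decorated permutations: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovfusion)
```

This vignette records the model the package implements, the conventions it
fixes where the mathematics leaves genuine freedom, and the numerical choices
behind the code. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The model

An agent is a 6-tuple `(X, G, W, P, D, A)` of three finite label sets and
three row-stochastic kernels: decision `D: X -> G`, action `A: G -> W`,
perception `P: W -> X`. All kernel algebra is finite matrix algebra; the
measure-theoretic generality of kernels on arbitrary sigma-algebras is
represented only by finite label sets, and the "aware subject" reading of the
experience space is represented only by its labels — nothing computable is
specified beyond that, so no sub-sigma-algebra machinery is provided.

The qualia kernel `Q = DAP` is square on `X` and captures sequential
experiencing. Two constructions combine agents:

* **Product** (`combine_product`): cartesian label products with Kronecker
  product kernels. We fix the label order to be lexicographic with the first
  agent major (labels pasted with `:`), which makes
  `qualia_kernel(a1 x a2) = Q1 %x% Q2` hold with R's own `kronecker()`
  block convention — the factored agent is block-diagonal, i.e.
  non-interacting.
* **Union with cross terms** (`combine_union`): `n` one-quale agents may
  interact through an arbitrary `n x n` row-stochastic cross-term matrix.
  For `n = 2` this is the family `m2_kernel(x, y)` with `x = p(2|1)`,
  `y = p(1|2)`. We accept any Markov matrix for any `n`, generalizing the
  two-agent case; whether every legal cross-term matrix is realized by some
  multi-agent network is left open, and `realize_agent()` provides only the
  single-agent witness `D = Q, A = P = I` (exact by construction).

## Flows, invariant measures, fusion

The discrete kernel derivative is `Q^2 - Q`; its rows sum to zero, and on
the two-state polytope its off-diagonals are
`(x(1-x-y), y(1-x-y))`. The identity `(0,0)` is the unique source, the
anti-diagonal `x + y = 1` the line of sinks; the only idempotent two-state
kernels are the identity and that fusion line (both facts are verified on a
grid plus exact boundary points in the tests).

`kernel_flow()` returns `lim Q^m` **algebraically**, not by iterating
powers: recurrent rows get their class's stationary vector (a linear solve on
the class block with the normalization replacing one redundant equation),
transient rows mix those vectors with absorption probabilities obtained from
`(I - Q_TT) h = Q_TC 1`. Iteration cannot certify a limit and converges
slowly for stiff chains; the algebraic route is exact up to the linear
solver. When a recurrent class is periodic the power limit does not exist and
a periodicity report is returned instead; the Cesàro mode uses the same
formula and always exists, since per-class Cesàro averages converge to the
same stationary vectors regardless of period.

Extremal invariant measures are returned one per recurrent class, in class
order (classes sorted by smallest state label) for deterministic output.
Fusion is the rank drop to a rank-one idempotent: `fuse()` distinguishes
"not idempotent" from "rank > 1" in its errors, and `fusion_kernel()` is its
exact inverse on the fusion simplex.

One bookkeeping clash is worth recording: parameterizing the two-state fusion
line by `alpha = x = 1 - y` indexes the *second* column of the stationary
kernel's rows `(1 - x, x)`, while the invariant measure convention
`mu = (alpha, 1 - alpha)` weights the *first* state. We therefore
parameterize fusion points by the invariant measure `mu` throughout, and
treat the line coordinate as the simplex coordinate of the second label.

## The decorated-permutation projection

A decorated permutation maps `{1..n}` injectively into `{1..2n}` with
`a <= sigma(a) <= a + n` and bijective mod-`n` reduction (residues in
`{1..n}`; all labels are 1-based, matching every printed example).

The Markov labeling sets `sigma(a) = a` for transient `a`. For recurrent
`a` the *literal* clause "first `b > a` whose inclusive window `(a,...,b)`
contains the class" would give `b = a + 1` for an absorbing state,
contradicting the stated absorbing value `a + n`. We therefore use a unified
window rule: the first `b > a` **that itself reduces into the class mod
`n`** and whose window covers the class. This reproduces the absorbing
convention (`b = a + n`), every image of the nine-state worked example
`[8,11,4,12,10,15,9,14,16]`, its transient variant, and both corner cells of
the two-state polytope. The label depends only on the support pattern of the
kernel, which is what makes the finite cell census below possible.

For arbitrary digraphs, classes are replaced by strongly connected
components. Singleton components need a convention the component rule cannot
supply: a node whose only edge is its self-loop maps to `a + n`
(absorbing-like); an isolated node maps to `a`; a singleton component with
edges to other nodes maps to `a` (transient-like). With this convention the
graph labeling agrees with the Markov labeling on support digraphs whose
non-singleton components are all recurrent — in particular on all
deterministic kernels and all dense kernels. A kernel with a non-singleton
*transient* class is labeled differently by the two definitions (window rule
vs transient rule); we follow each definition on its own domain rather than
force agreement.

The Grassmannian labeling doubles the columns of a full-rank `k x n` matrix
and assigns each column the first later column index whose span absorbs it,
with zero columns mapping to themselves. Span membership is a rank
comparison at relative tolerance `1e-9`.

## Bridges and diagrams

Bridge decomposition repeatedly extracts the lexicographically first pair
`(a, c)` with `a < c`, `sigma(a) < sigma(c)`, and all strictly intermediate
numbers decorated fixed points, then exchanges the images at `a` and `c`.
Two conventions are fixed here:

* **Endpoints must not be decorated fixed points.** Without this, inputs
  such as `[1,3,5]` (n = 3) admit a "bridge" at the fixed point 1 that
  un-fixes it, and the process never reaches an identity decoration. With
  it, the decomposition of `[3,5,4,6,7]` is exactly
  `(12)(23)(24)(12)(25)` and terminates for every decorated permutation
  (exhaustively checked through `n = 4`, with lengths matching a
  breadth-first-search minimality oracle).
* **Swap semantics**: the recorded transposition exchanges the images at
  positions `a` and `c` after recording. This convention uniquely reproduces
  the printed chain above and is locked by that test.

The diagram builder hangs each bridge below the previous one: a white node
on the column of `a`, a black node on the column of `c`, a horizontal edge
between them, and vertical column edges in extraction order; untouched legs
become lollipops colored by the residual decoration. The planar embedding is
stored as an explicit rotation system (edges counterclockwise per node,
computed once from coordinates). Trip reading then needs no geometry: "turn
left at white" is the previous edge in counterclockwise order, "turn right
at black" the next, and degree-2 nodes are passed straight through. This
orientation convention is the one consistent with the published leg-by-leg
walkthrough for `[3,4,5,6]` (1 to 3, 2 to 4, 3 to 1 plus `n`), which the
acceptance tests pin down. `simplify_diagram()` removes degree-2 nodes by
patching the rotation system in place — a purely combinatorial operation, so
trips are provably unchanged — and diagram equality in tests is
trip-equivalence, not graph isomorphism, since diagrams are only meaningful
up to moves. No general planarity checker is implemented; planarity holds by
construction order.

## The polytope census

`Mn` has dimension `n(n-1)` and `n^n` vertices (a product of `n` unit
`(n-1)`-simplices; we follow this product-of-simplices reading where a prose
passage elsewhere describes `Mn` as an `n`-cube, which conflicts with it for
`n >= 3`). Vertex adjacency is the differ-in-exactly-one-row rule — the edge
rule of a product of simplices — giving a regular graph of degree `n(n-1)`.

Because the cell label depends only on the support pattern, the full cell
census is a finite enumeration of `(2^n - 1)^n` row supports rather than a
sampling of the continuum. For `n = 2` this yields exactly the four cells
`[3,4]`, `[2,3]`, `[3,2]`, `[1,4]`. Note that under the coordinates
`x = p(2|1), y = p(1|2)`, the window rule places `[1,4]` on the `y = 0` edge
(state 2 absorbing) and `[3,2]` on `x = 0`; published figure text swaps the
two edge labels, and we follow the definition, which is also what the census
as a *set* confirms.

For `n = 3` the census finds **14** distinct decorated permutations over all
343 support patterns, and the same 14 over the 27 deterministic vertices,
regression-locked in the tests. An appendix of the source literature reports
17 for the vertices; the window rule assigns the same label to the two cyclic
orders of a 3-cycle (e.g. the two derangement vertices both label `[2,3,4]`'s
analogue), so a census distinguishing cycle order would count more. We
publish the computed census rather than force the count.

## Entropic arrow

`entropy_profile()` computes `H(X_n | X_1) = sum_a mu(a) H(Q^(n-1)[a, ])`
for `n = 2..N` with `0 log 0 := 0`, in bits by default. The start
distribution must be invariant — that is the only reading under which the
marginal entropy is constant for every kernel — so a supplied non-stationary
start is rejected with an error, and when several invariant measures exist
the first extremal one is used with a warning unless a start is given.
Monotonicity of the profile and constancy of the marginal are theorems
(conditioning reduces uncertainty, plus the Markov property and
homogeneity); `check_arrow()` verifies both anyway at tolerance `1e-10` and
flags any violation as an implementation bug, not a property of the input.

## Numerical choices

* Row-sum validation tolerance `tol_row = 1e-9`; rows within tolerance are
  renormalized exactly to 1, larger deviations are errors naming the row.
* Structural zeros: entries `<= tol_zero` (default exactly 0) are excluded
  from the support digraph; configurable because renormalization can leave
  dust of order machine epsilon.
* Idempotence and fusion-rank tolerances default to `1e-9`; Grassmannian
  rank tests use relative tolerance `1e-9`. All are overridable arguments.
* All computation is double precision. An exact-rational mode was
  considered and not built: R has no native rationals, and integer or 0/1
  kernels — every printed worked case — are exactly representable in
  doubles, so the reference values are reproduced bit-exactly anyway.
* Linear solves (stationary vectors, absorption probabilities) use dense LU
  on class blocks; solver dust below `1e-12` in stationary vectors is
  clipped to zero before normalization.

## The fixture generator

`make_fixtures()` defines the study conditions for the property tests:

* `dirichlet` — rows from the flat Dirichlet (all concentrations 1), the
  uniform distribution on the simplex: dense, irreducible, aperiodic with
  probability one. Used for algebraic identities (Kronecker factorization,
  entropic arrow) at `n = 2..5`, 100 kernels per property.
* `deterministic` — 0/1 kernels, i.e. polytope vertices, enumerated
  exhaustively or sampled without replacement. Exercises periodic classes
  and the vertex census.
* `support-pattern` — random non-empty row supports with uniform positive
  entries: reducible chains with transient states, exercising class
  analysis, flows, and cell labels across all cells.

Fixtures are seed-deterministic and generated at test time; nothing is
stored on disk. What the generator does **not** emulate: near-degenerate
kernels (rows summing to 1 only within large error), ill-conditioned
almost-reducible chains where entries straddle `tol_zero`, and large state
spaces — the exhaustive guarantees (round trips through `n = 4`, censuses
through `n = 3`, decoration counts through `n = 5`) are exact but finite,
and say nothing about asymptotics in `n`.

## Scope and limitations

The package stops at the combinatorial boundary: no Plücker coordinates,
positroid geometry, amplituhedron volumes, scattering amplitudes, or
differential forms; no square/merge diagram moves beyond degree-2
elimination; no continuous-time or infinite state spaces. The correspondence
between a communicating class of size `l` and an `(l-1)`-dimensional
subspace is not asserted anywhere in code, since no procedure for it is
specified. Test problem sizes (exhaustive `n <= 4` for diagrams, `n <= 7`
for random projections, horizons `N <= 60` for entropy) were chosen as the
smallest sizes at which every structural claim is exercised exhaustively or
with substantial randomization.
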