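# markovfusion

Finite Markov-kernel machinery for the dynamics of interacting agents, and
its combinatorial projection to decorated permutations and bicolored planar
(plabic / on-shell) diagrams.

The package is aimed at researchers in mathematical consciousness science and
Markov-chain combinatorics who want a tested implementation of the following
circle of ideas:

* An **agent** is a 6-tuple `(X, G, W, P, D, A)`: finite sets of experiences
  `X`, actions `G`, and world states `W`, linked by row-stochastic kernels
  `D: X -> G` (decision), `A: G -> W` (action), and `P: W -> X` (perception).
  Its **qualia kernel** `Q = DAP` is a Markov kernel on `X` describing the
  agent's sequential experiencing.
* The set of all `n x n` row-stochastic matrices is the **Markov polytope**
  `Mn`, a product of `n` simplices of dimension `n(n-1)` with `n^n`
  deterministic vertices. The discrete kernel derivative `Q^2 - Q` defines a
  flow on `Mn`; for `n = 2`, with coordinates `x = p(2|1)`, `y = p(1|2)`, the
  flow is `(dx, dy) = (x(1-x-y), y(1-x-y))`, with source at the identity
  `(0,0)` and a line of sinks on `x + y = 1`.
* Kernels on that sink line are idempotent and rank one (all rows equal): the
  `n` qualia **fuse** into a single mixture quale. The rank-one stationary
  kernels form the **fusion simplex** `Fn`, a unit `(n-1)`-simplex.
* Every kernel projects to a **decorated permutation**
  `sigma: {1..n} -> {1..2n}` computed from its communicating classes
  (transient states map to themselves; a recurrent state maps to the first
  later position whose cyclic window covers its class; absorbing states map
  to `a + n`). The same labeling applies to directed graphs (via strongly
  connected components) and to full-rank `k x n` matrices (via column spans,
  the positive-Grassmannian cell label).
* A decorated permutation decomposes into a minimal chain of **adjacent
  transpositions** (BCFW bridges), from which a reduced **on-shell diagram**
  is built; trips through the diagram (turn left at white nodes, right at
  black) read the permutation back off.
* A homogeneous chain started from an invariant measure has constant marginal
  entropy `H(X_n)`, yet conditioning on the first state yields a monotone
  **entropic arrow**: `H(X_n | X_1)` is non-decreasing in `n`.

## Worked example

```r
library(markovfusion)

Q <- m2_kernel(0.5, 0.25)   # two-state kernel with cross terms x = 0.5, y = 0.25
communicating_classes(Q)
#> 1 communicating class(es)
#>   {1,2}: recurrent, period 1

kernel_flow(Q)              # exact limit of Q^m
#> Markov kernel (2 x 2, square)
#>        1      2
#> 1 0.3333 0.6667
#> 2 0.3333 0.6667

fuse(kernel_flow(Q))        # the flow is rank one: the two qualia have fused
#> fusion point ( 0.333333, 0.666667 )
```

The flow lands on the fusion line `x + y = 1`; its common row `(1/3, 2/3)` is
the invariant measure of `Q`, i.e. the mixture weights of the new single
quale.

Projection to decorated permutations, on the 9-state deterministic chain
whose cycles are `(158), (2), (34), (6), (79)`:

```r
dperm_from_markov(deterministic_kernel(c(5, 2, 4, 3, 8, 6, 9, 1, 7)))
#> decorated permutation [8,11,4,12,10,15,9,14,16]
```

States `2` and `6` are absorbing (`sigma(a) = a + 9`), and each cycle maps
into its own class. Bridge decomposition and the entropic arrow:

```r
bridge_decompose(parse_sigma("[3,5,4,6,7]"))
#> bridge decomposition of [3,5,4,6,7]
#>   (12)(23)(24)(12)(25)
#>   residual: [6,7,3,4,5]

entropy_profile(kernel(rbind(c(.9, .1), c(.1, .9))), N = 5)
#>   n H_conditional H_marginal
#> 1 2     0.4689956          1
#> 2 3     0.6800770          1
#> 3 4     0.8016291          1
#> 4 5     0.8753440          1
```

The conditional entropies (bits) grow toward the constant marginal entropy of
the stationary distribution — the arrow of time induced by conditioning.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/markovfusion.R summary --n 3
# {"dimension":6,"vertices":27}
Rscript inst/cli/markovfusion.R decompose --sigma "[3,5,4,6,7]"
# (12)(23)(24)(12)(25)
```

Subcommands: `validate`, `classify`, `decorate`, `decompose`, `diagram`,
`flow`, `fuse`, `combine`, `entropy`, `cells`, `summary`, `fixtures`.

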