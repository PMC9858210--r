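#' Seeded kernel fixture generator
#'
#' Deterministically generates families of kernels for tests and simulations;
#' identical arguments give identical fixtures.
#'
#' * `"dirichlet"`: each row drawn from the flat Dirichlet on the simplex
#'   (all concentration parameters 1) — dense, irreducible with probability
#'   one.
#' * `"deterministic"`: 0/1 kernels. When `count` equals `n^n` (or is `NULL`)
#'   all vertices of the polytope are enumerated in order; otherwise `count`
#'   vertices are sampled without replacement.
#' * `"support-pattern"`: each row gets a uniformly chosen non-empty support
#'   subset, then uniform positive entries on the support, normalized —
#'   exercises all cells of the polytope.
#'
#' @param n Number of states.
#' @param count Number of kernels.
#' @param seed Integer seed.
#' @param family One of `"dirichlet"`, `"deterministic"`,
#'   `"support-pattern"`.
#' @return List of `markov_kernel` objects.
#' @export
make_fixtures <- function(n, count = 1L,
                          seed = 1L,
                          family = c("dirichlet", "deterministic",
                                     "support-pattern")) {
  n <- check_n(n)
  family <- match.arg(family)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  if (family == "deterministic") {
    total <- n^n
    if (is.null(count) || count == total) {
      return(polytope_vertices(n))
    }
    codes <- sample.int(total, size = count, replace = FALSE) - 1L
    return(lapply(codes, function(code)
      deterministic_kernel(vertex_map(code, n), n)))
  }

  lapply(seq_len(count), function(i) {
    m <- matrix(0, n, n)
    for (r in seq_len(n)) {
      if (family == "dirichlet") {
        g <- stats::rgamma(n, shape = 1)  # flat Dirichlet via gamma ratios
        m[r, ] <- g / sum(g)
      } else {
        s <- which(stats::runif(n) < 0.5)
        if (length(s) == 0L) s <- sample.int(n, 1L)
        w <- stats::runif(length(s))
        m[r, s] <- w / sum(w)
      }
    }
    kernel(m)
  })
}
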