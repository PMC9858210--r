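# Independent oracles and small combinatorial helpers used across tests.

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

all_decorated_perms <- function(n) {
  out <- list()
  for (p in all_perms(n)) {
    out <- c(out, decorations_of(p))
  }
  out
}

# invariant measures by a route independent of the package's linear solver:
# boolean-matrix reachability for the class structure, then Cesaro averaging
# of the restricted chain for each recurrent class's stationary vector.
# iters = 2520 = lcm(1..9): Cesaro sums over whole periods, so deterministic
# cycles of length <= 9 give their uniform stationary vector exactly.
oracle_invariant_measures <- function(Q, iters = 2520) {
  m <- unclass(Q)
  n <- nrow(m)
  supp <- m > 0
  R <- diag(n) > 0 | supp
  for (step in seq_len(n)) R <- R | ((R %*% R) > 0)
  comm <- R & t(R)
  seen <- rep(FALSE, n)
  out <- list()
  for (a in seq_len(n)) {
    if (seen[a]) next
    cl <- which(comm[a, ])
    seen[cl] <- TRUE
    recurrent <- all(R[cl, , drop = FALSE] <= comm[cl, , drop = FALSE])
    if (!recurrent) next
    P <- m[cl, cl, drop = FALSE]
    v <- rep(1 / length(cl), length(cl))
    acc <- numeric(length(cl))
    for (i in seq_len(iters)) {
      v <- as.numeric(v %*% P)
      acc <- acc + v
    }
    mu <- rep(0, n)
    mu[cl] <- acc / sum(acc)
    out[[length(out) + 1L]] <- mu
  }
  out
}

# minimal number of adjacent transpositions reducing sigma to a decoration of
# the identity, by breadth-first search over all legal swaps (not just the
# lexicographically first one).
oracle_min_bridge_length <- function(sigma) {
  n <- sigma$n
  a_idx <- seq_len(n)
  key <- function(img) paste(img, collapse = ",")
  is_done <- function(img) all(img == a_idx | img == a_idx + n)
  moves <- function(img) {
    fixedish <- img == a_idx | img == a_idx + n
    res <- list()
    for (a in seq_len(n - 1L)) {
      if (fixedish[a]) next
      for (cc in (a + 1L):n) {
        if (fixedish[cc]) next
        if (a + 1L <= cc - 1L && !all(fixedish[(a + 1L):(cc - 1L)])) break
        if (img[a] < img[cc]) {
          nxt <- img
          nxt[c(a, cc)] <- img[c(cc, a)]
          res[[length(res) + 1L]] <- nxt
        }
        break
      }
    }
    res
  }
  frontier <- list(sigma$images)
  visited <- new.env(parent = emptyenv())
  assign(key(sigma$images), TRUE, envir = visited)
  depth <- 0L
  repeat {
    if (any(vapply(frontier, is_done, logical(1)))) return(depth)
    nxt <- list()
    for (img in frontier) {
      for (mv in moves(img)) {
        k <- key(mv)
        if (!exists(k, envir = visited)) {
          assign(k, TRUE, envir = visited)
          nxt[[length(nxt) + 1L]] <- mv
        }
      }
    }
    if (length(nxt) == 0L) stop("BFS exhausted without reaching an identity decoration")
    frontier <- nxt
    depth <- depth + 1L
  }
}

# the nine-state deterministic chain whose cycles are (158), (2), (34), (6), (79)
chain9 <- function() deterministic_kernel(c(5, 2, 4, 3, 8, 6, 9, 1, 7))
chain9_transient2 <- function() deterministic_kernel(c(5, 1, 4, 3, 8, 6, 9, 1, 7))

# split a random edge of a diagram with a degree-2 node, preserving rotation
insert_degree2_node <- function(d, edge_row) {
  e <- d$edges$id[edge_row]
  u <- d$edges$from[edge_row]
  v <- d$edges$to[edge_row]
  id <- nrow(d$nodes) + 1L
  d$nodes <- rbind(d$nodes, data.frame(
    id = id, kind = "internal",
    color = sample(c("white", "black"), 1L),
    x = (d$nodes$x[u] + d$nodes$x[v]) / 2,
    y = (d$nodes$y[u] + d$nodes$y[v]) / 2,
    leg = NA_integer_, stringsAsFactors = FALSE))
  e1 <- max(d$edges$id) + 1L
  e2 <- e1 + 1L
  d$edges <- rbind(d$edges[-edge_row, ],
                   data.frame(id = c(e1, e2), from = c(u, id), to = c(id, v)))
  ru <- d$rotation[[u]]; ru[ru == e] <- e1; d$rotation[[u]] <- ru
  rv <- d$rotation[[v]]; rv[rv == e] <- e2; d$rotation[[v]] <- rv
  d$rotation[[id]] <- c(e1, e2)
  d
}

expect_sigma <- function(object, expected) {
  expect_equal(format_sigma(object), expected)
}
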