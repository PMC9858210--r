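#' Bridge decomposition of a decorated permutation
#'
#' Decomposes a decorated permutation into a minimal sequence of *adjacent
#' transpositions* (BCFW bridges). Repeatedly find the lexicographically
#' first pair `(a, c)` such that `a < c`, neither `a` nor `c` is a decorated
#' fixed point, `sigma(a) < sigma(c)`, and every number strictly between `a`
#' and `c` is mapped to itself or to itself plus `n`; record `(a, c)` and
#' exchange the images at positions `a` and `c`. The process terminates when
#' only a decoration of the identity remains.
#'
#' @param sigma A `decorated_perm`.
#' @return An object of class `bridge_decomposition`: a list with
#'   `transpositions` (two-column integer matrix, one bridge per row, in
#'   extraction order), `residual` (the final decoration of the identity),
#'   `sigma` (the input), and `n`.
#' @examples
#' bridge_decompose(decorated_perm(c(3, 5, 4, 6, 7)))
#' # transpositions (1,2),(2,3),(2,4),(1,2),(2,5)
#' @export
bridge_decompose <- function(sigma) {
  stopifnot(inherits(sigma, "decorated_perm"))
  n <- sigma$n
  cur <- sigma$images
  a_idx <- seq_len(n)
  trans <- matrix(integer(), 0L, 2L)
  guard <- 0L
  repeat {
    fixedish <- cur == a_idx | cur == a_idx + n
    if (all(fixedish)) break
    found <- FALSE
    for (a in seq_len(n - 1L)) {
      if (fixedish[a]) next
      for (cc in (a + 1L):n) {
        if (fixedish[cc]) {
          next  # c must be a moved element, but may be skipped over
        }
        if (a + 1L <= cc - 1L && !all(fixedish[(a + 1L):(cc - 1L)]))
          break   # a gap of moved elements blocks every larger c
        if (cur[a] < cur[cc]) {
          trans <- rbind(trans, c(a, cc))
          tmp <- cur[a]; cur[a] <- cur[cc]; cur[cc] <- tmp
          found <- TRUE
        }
        break     # lexicographic-first c for this a is decided either way
      }
      if (found) break
    }
    if (!found)
      stop("no adjacent transposition available before reaching an identity decoration")
    guard <- guard + 1L
    if (guard > n * n)
      stop("bridge decomposition failed to terminate (internal error)")
  }
  structure(list(
    transpositions = trans,
    residual = decorated_perm(cur, n),
    sigma = sigma,
    n = n
  ), class = "bridge_decomposition")
}

#' @export
print.bridge_decomposition <- function(x, ...) {
  cat("bridge decomposition of", format_sigma(x$sigma), "\n")
  if (nrow(x$transpositions) == 0L) {
    cat("  (already a decoration of the identity)\n")
  } else {
    cat(" ", paste(sprintf("(%d%d)", x$transpositions[, 1L],
                           x$transpositions[, 2L]), collapse = ""), "\n")
  }
  cat("  residual:", format_sigma(x$residual), "\n")
  invisible(x)
}

new_diagram <- function(n) {
  list(
    n = n,
    nodes = data.frame(id = seq_len(n), kind = "leg",
                       color = NA_character_,
                       x = as.numeric(seq_len(n)), y = 0, leg = seq_len(n),
                       stringsAsFactors = FALSE),
    edges = data.frame(id = integer(), from = integer(), to = integer()),
    rotation = vector("list", n)
  )
}

add_node <- function(d, kind, color, x, y) {
  id <- nrow(d$nodes) + 1L
  d$nodes <- rbind(d$nodes, data.frame(
    id = id, kind = kind, color = color, x = x, y = y, leg = NA_integer_,
    stringsAsFactors = FALSE))
  d$rotation[[id]] <- integer()
  list(d = d, id = id)
}

add_edge <- function(d, from, to) {
  id <- if (nrow(d$edges) == 0L) 1L else max(d$edges$id) + 1L
  d$edges <- rbind(d$edges, data.frame(id = id, from = from, to = to))
  d
}

# screen coordinates have y growing downward; flip y so that angles follow
# the usual counterclockwise convention
edge_angle <- function(d, node, e) {
  other <- if (d$edges$from[match(e, d$edges$id)] == node)
    d$edges$to[match(e, d$edges$id)] else d$edges$from[match(e, d$edges$id)]
  dx <- d$nodes$x[other] - d$nodes$x[node]
  dy <- d$nodes$y[other] - d$nodes$y[node]
  (atan2(-dy, dx) * 180 / pi) %% 360
}

# order each node's incident edges counterclockwise from coordinates
build_rotation <- function(d) {
  for (v in d$nodes$id) {
    inc <- d$edges$id[d$edges$from == v | d$edges$to == v]
    if (length(inc) > 1L) {
      ang <- vapply(inc, function(e) edge_angle(d, v, e), numeric(1))
      inc <- inc[order(ang)]
    }
    d$rotation[[v]] <- inc
  }
  d
}

#' Construct a bridge (on-shell, plabic) diagram
#'
#' Builds the planar bicolored diagram of a bridge decomposition: the `n`
#' boundary legs sit on top; each transposition `(a, c)` hangs a white node on
#' the vertical line of leg `a` and a black node on the line of leg `c`,
#' joined by a horizontal bridge, with column lines extended downward in
#' extraction order. A leg absent from every transposition gets a lollipop —
#' white when the residual maps it to itself, black when to itself plus `n`.
#' The planar embedding is stored as an explicit rotation system (edges in
#' counterclockwise order at each node).
#'
#' @param decomp A `bridge_decomposition`, or a `decorated_perm` (decomposed
#'   first).
#' @return An object of class `bridge_diagram`: list with `n`, `nodes`,
#'   `edges`, `rotation`.
#' @export
build_diagram <- function(decomp) {
  if (inherits(decomp, "decorated_perm")) decomp <- bridge_decompose(decomp)
  stopifnot(inherits(decomp, "bridge_decomposition"))
  n <- decomp$n
  d <- new_diagram(n)
  bottom <- seq_len(n)  # current lowest node of each leg column
  trans <- decomp$transpositions
  for (k in seq_len(nrow(trans))) {
    a <- trans[k, 1L]; cc <- trans[k, 2L]
    r <- add_node(d, "internal", "white", a, k); d <- r$d; w <- r$id
    r <- add_node(d, "internal", "black", cc, k); d <- r$d; b <- r$id
    d <- add_edge(d, bottom[a], w)
    d <- add_edge(d, bottom[cc], b)
    d <- add_edge(d, w, b)
    bottom[a] <- w
    bottom[cc] <- b
  }
  touched <- if (nrow(trans) > 0L) unique(as.vector(trans)) else integer()
  for (leg in setdiff(seq_len(n), touched)) {
    col <- if (decomp$residual$images[leg] == leg) "white" else "black"
    r <- add_node(d, "internal", col, leg, 0.5); d <- r$d
    d <- add_edge(d, leg, r$id)
  }
  d <- build_rotation(d)
  structure(d, class = "bridge_diagram")
}

#' @export
print.bridge_diagram <- function(x, ...) {
  internal <- x$nodes[x$nodes$kind == "internal", ]
  cat(sprintf("bridge diagram: %d legs, %d internal nodes (%d white, %d black), %d edges\n",
              x$n, nrow(internal), sum(internal$color == "white"),
              sum(internal$color == "black"), nrow(x$edges)))
  invisible(x)
}

diagram_degree <- function(d) {
  vapply(d$rotation, length, integer(1))
}

#' Read the decorated permutation off a diagram
#'
#' Walks the trip from each boundary leg: pass straight through any degree-2
#' node, turn left at a white node, right at a black node, until another leg
#' is reached. A trip from `i` ending at `e` gives `sigma(i) = e` when
#' `e > i` and `e + n` when `e < i`; a lollipop resolves the fixed-point
#' decoration (white keeps `i`, black gives `i + n`).
#'
#' @param d A `bridge_diagram`.
#' @return A `decorated_perm`.
#' @export
read_perm <- function(d) {
  stopifnot(inherits(d, "bridge_diagram"))
  n <- d$n
  deg <- diagram_degree(d)
  images <- integer(n)
  for (i in seq_len(n)) {
    if (deg[i] != 1L)
      stop(sprintf("boundary leg %d must have exactly one incident edge", i))
    e <- d$rotation[[i]]
    v <- edge_other(d, e, i)
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 4L * (nrow(d$edges) + 1L))
        stop("trip failed to terminate (malformed diagram)")
      if (d$nodes$kind[v] == "leg") {
        end <- d$nodes$leg[v]
        images[i] <- if (end > i) end else if (end < i) end + n else i
        break
      }
      rot <- d$rotation[[v]]
      if (length(rot) == 1L) {           # lollipop: decoration from color
        images[i] <- if (d$nodes$color[v] == "white") i else i + n
        break
      }
      if (length(rot) == 2L) {           # bipartite node: straight through
        e <- rot[rot != e]
      } else {
        p <- match(e, rot)
        len <- length(rot)
        e <- if (d$nodes$color[v] == "white")
          rot[((p - 2L) %% len) + 1L]    # next clockwise: turn left
        else
          rot[(p %% len) + 1L]           # next counterclockwise: turn right
      }
      v <- edge_other(d, e, v)
    }
  }
  decorated_perm(images, n)
}

edge_other <- function(d, e, v) {
  row <- match(e, d$edges$id)
  if (d$edges$from[row] == v) d$edges$to[row] else d$edges$from[row]
}

#' Eliminate bipartite (degree-2) nodes
#'
#' Repeatedly removes internal degree-2 nodes, merging their two incident
#' edges; the rotation system of the neighbours is patched in place, so every
#' trip — and hence [read_perm()] — is unchanged. Lollipops and trivalent
#' nodes are kept.
#'
#' @param d A `bridge_diagram`.
#' @return The simplified `bridge_diagram`.
#' @export
simplify_diagram <- function(d) {
  stopifnot(inherits(d, "bridge_diagram"))
  repeat {
    deg <- diagram_degree(d)
    cand <- which(d$nodes$kind == "internal" & deg == 2L)
    removed <- FALSE
    for (v in cand) {
      rot <- d$rotation[[v]]
      u1 <- edge_other(d, rot[1L], v)
      u2 <- edge_other(d, rot[2L], v)
      if (u1 == v || u2 == v || u1 == u2) next  # avoid creating self-loops
      id <- max(d$edges$id) + 1L
      d$edges <- rbind(d$edges[!d$edges$id %in% rot, ],
                       data.frame(id = id, from = u1, to = u2))
      r1 <- d$rotation[[u1]]; r1[r1 == rot[1L]] <- id; d$rotation[[u1]] <- r1
      r2 <- d$rotation[[u2]]; r2[r2 == rot[2L]] <- id; d$rotation[[u2]] <- r2
      d$rotation[[v]] <- integer()
      d$nodes$kind[v] <- "removed"
      removed <- TRUE
      break
    }
    if (!removed) break
  }
  # removed nodes stay as tombstone rows so node ids keep indexing rows
  structure(d, class = "bridge_diagram")
}

#' Export a diagram as Graphviz DOT
#'
#' White internal nodes are drawn as white-filled circles, black nodes as
#' black-filled circles; boundary legs as plain labels.
#'
#' @param d A `bridge_diagram`.
#' @return A character scalar containing the DOT source.
#' @export
diagram_dot <- function(d) {
  stopifnot(inherits(d, "bridge_diagram"))
  lines <- c("graph bridge_diagram {")
  for (r in which(d$nodes$kind != "removed")) {
    nd <- d$nodes[r, ]
    lines <- c(lines, if (nd$kind == "leg") {
      sprintf('  n%d [shape=plaintext, label="%d"];', nd$id, nd$leg)
    } else {
      sprintf('  n%d [shape=circle, style=filled, fillcolor=%s, label=""];',
              nd$id, nd$color)
    })
  }
  for (r in seq_len(nrow(d$edges))) {
    lines <- c(lines, sprintf("  n%d -- n%d;", d$edges$from[r], d$edges$to[r]))
  }
  paste(c(lines, "}"), collapse = "\n")
}
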