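test_that("polytope summary gives n(n-1) dimensions and n^n vertices", {
  expect_equal(polytope_summary(2), list(dimension = 2L, vertex_count = 4))
  expect_equal(polytope_summary(3)$vertex_count, 27)
  expect_equal(polytope_summary(3)$dimension, 6L)
  expect_error(polytope_summary(0), "n must be")
})

test_that("vertex enumeration lists all deterministic kernels", {
  v2 <- polytope_vertices(2)
  expect_length(v2, 4L)
  mats <- lapply(v2, function(k) unname(unclass(k)))
  expect_true(any(vapply(mats, identical, TRUE, diag(2))))           # identity
  expect_true(any(vapply(mats, identical, TRUE,
                         rbind(c(0, 1), c(1, 0)))))                  # NOT
  expect_true(any(vapply(mats, identical, TRUE,
                         rbind(c(1, 0), c(1, 0)))))                  # constant
  expect_length(polytope_vertices(3), 27L)
  expect_length(polytope_vertices(4), 256L)
  expect_error(polytope_vertices(7), "refusing")
})

test_that("vertex adjacency is the differ-in-one-row rule", {
  g2 <- vertex_adjacency(2)
  expect_equal(igraph::vcount(g2), 4)
  expect_true(all(igraph::degree(g2) == 2))   # the unit square is a 4-cycle
  expect_equal(igraph::girth(g2)$girth, 4)

  g3 <- vertex_adjacency(3)
  expect_equal(igraph::vcount(g3), 27)
  expect_true(all(igraph::degree(g3) == 6))   # regular of degree n(n-1)

  # identity and NOT differ in both rows, so they are not adjacent
  v2 <- polytope_vertices(2)
  id_i <- which(vapply(v2, function(k) identical(unname(unclass(k)), diag(2)),
                       TRUE))
  not_i <- which(vapply(v2, function(k)
    identical(unname(unclass(k)), rbind(c(0, 1), c(1, 0))), TRUE))
  expect_false(igraph::are_adjacent(g2, id_i, not_i))
})

test_that("cell labels follow the Markov projection", {
  expect_sigma(cell_of(kernel(diag(2))), "[3,4]")
  expect_sigma(cell_of(m2_kernel(1, 1)), "[2,3]")
  expect_sigma(cell_of(m2_kernel(0.3, 0.6)), "[2,3]")  # interior
  expect_sigma(cell_of(kernel(rbind(c(1, 0), c(.5, .5)))), "[3,2]")
})

test_that("support-pattern census finds the four cells of the unit square", {
  census <- enumerate_support_cells(2)
  expect_setequal(names(census), c("[3,4]", "[2,3]", "[3,2]", "[1,4]"))
  expect_equal(sum(census), 9)               # (2^2 - 1)^2 support patterns
  expect_equal(census[["[3,4]"]], 1L)        # identity support only

  expect_equal(names(enumerate_support_cells(1)), "[2]")
})

test_that("three-state support census is locked and covers all patterns", {
  census <- enumerate_support_cells(3)
  expect_length(census, 14L)
  expect_equal(sum(census), 343)             # (2^3 - 1)^3 patterns
  # every vertex cell appears in the census
  vertex_cells <- unique(vapply(polytope_vertices(3), function(v)
    format_sigma(dperm_from_markov(v)), ""))
  expect_true(all(vertex_cells %in% names(census)))
  expect_length(vertex_cells, 14L)
})

test_that("fusion kernels are rank-one stationary kernels with the right measure", {
  fk <- fusion_kernel(c(0.7, 0.3))
  expect_equal(unname(unclass(fk)), rbind(c(.7, .3), c(.7, .3)))
  expect_true(is_idempotent(fk))
  expect_equal(unname(invariant_measures(fk)[[1]]), c(0.7, 0.3))

  fk3 <- fusion_kernel(c(1, 0, 0))
  expect_equal(unname(unclass(fk3)), matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0), 3))

  # the Cesaro flow of NOT is the barycentric fusion kernel
  expect_equal(unclass(kernel_flow(m2_kernel(1, 1), "cesaro")),
               unclass(fusion_kernel(c(0.5, 0.5))))
})

test_that("fuse extracts weights and distinguishes failure causes", {
  w <- fuse(kernel(rbind(c(.7, .3), c(.7, .3))))
  expect_equal(unname(unclass(w)), c(0.7, 0.3))
  expect_error(fuse(kernel(diag(2))), "rank > 1")
  expect_error(fuse(m2_kernel(0.3, 0.2)), "not idempotent")

  # round trips both ways
  for (wts in list(c(.2, .8), c(.1, .4, .5), c(1, 0))) {
    expect_equal(unname(unclass(fuse(fusion_kernel(wts)))), wts)
  }
  # flow of an interior kernel fuses to its invariant measure
  f <- kernel_flow(m2_kernel(0.4, 0.4))
  expect_equal(unname(unclass(fuse(f))),
               unname(invariant_measures(m2_kernel(0.4, 0.4))[[1]]))
})

test_that("invariant-measure lines through the origin have slope a/(1-a)", {
  expect_equal(invariant_line_slope(1 / 3), 0.5)
  expect_equal(invariant_line_slope(0.5), 1)
  expect_equal(invariant_line_slope(2 / 3), 2)
  expect_error(invariant_line_slope(0), "strictly between")
  expect_error(invariant_line_slope(1), "strictly between")

  # every kernel on the alpha-line has invariant measure (alpha, 1 - alpha)
  for (alpha in seq(0.1, 0.9, by = 0.1)) {
    slope <- invariant_line_slope(alpha)
    for (x in seq(0.1, 0.5, length.out = 5)) {
      y <- slope * x
      if (y > 1) next
      mu <- invariant_measures(m2_kernel(x, y))[[1]]
      expect_equal(unname(mu), c(alpha, 1 - alpha), tolerance = 1e-12)
    }
  }
})

test_that("flow field vanishes exactly at the source and on the fusion line", {
  ff <- flow_field_m2(11)
  expect_s3_class(ff, "flow_field_m2")
  at <- function(x, y) ff[abs(ff$x - x) < 1e-9 & abs(ff$y - y) < 1e-9, ]
  expect_equal(unlist(at(0, 0)[c("dx", "dy")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(at(0.5, 0.5)[c("dx", "dy")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(at(0.2, 0.2)[c("dx", "dy")], use.names = FALSE),
               c(0.12, 0.12))
  zero <- abs(ff$dx) < 1e-12 & abs(ff$dy) < 1e-12
  on_locus <- (ff$x == 0 & ff$y == 0) | abs(ff$x + ff$y - 1) < 1e-12
  # the vector field also vanishes on the polytope edges x = 0 and y = 0 in
  # one coordinate; jointly zero exactly on the source and the fusion line
  expect_equal(zero, on_locus | (ff$x == 0 & ff$y == 0))
  expect_error(flow_field_m2(1), "at least 2")
})

test_that("qualia mixing is the convex combination of palette colors", {
  pal <- rbind(red = c(1, 0, 0), green = c(0, 1, 0), blue = c(0, 0, 1))
  expect_equal(qualia_mix(c(red = 1, green = 0), pal), c(1, 0, 0))
  expect_equal(qualia_mix(c(red = .5, green = .5), pal), c(.5, .5, 0))
  bary <- fusion_point(c(red = 1, green = 1, blue = 1) / 3)
  expect_equal(qualia_mix(bary, pal), rep(1 / 3, 3))
  expect_error(qualia_mix(c(cyan = 1), pal), "no entry")
})

test_that("fusion points are simplex points", {
  expect_error(fusion_point(c(0.5, 0.4)), "sum to 1")
  expect_error(fusion_point(c(-0.1, 1.1)), "non-negative")
  fp <- fusion_point(c(a = 0.25, b = 0.75))
  expect_s3_class(fp, "fusion_point")
  expect_equal(sum(fp), 1)
})
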