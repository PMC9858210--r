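test_that("decorated permutation validation enforces range and mod-n bijectivity", {
  expect_s3_class(decorated_perm(c(3, 4, 5, 6)), "decorated_perm")
  expect_s3_class(decorated_perm(c(8, 11, 4, 12, 10, 15, 9, 14, 16)),
                  "decorated_perm")
  expect_error(decorated_perm(c(5, 2)), "range violation")
  expect_error(decorated_perm(c(1, 1)), "range violation")  # sigma(2) < 2
  expect_error(decorated_perm(c(2, 2)), "collision")
  expect_error(decorated_perm(c(1, 3)), "collision")
})

test_that("underlying permutation is the 1-based mod-n reduction", {
  expect_equal(underlying_perm(decorated_perm(c(3, 4, 5, 6))), c(3, 4, 1, 2))
  expect_equal(underlying_perm(decorated_perm(c(3, 4))), c(1, 2))
  expect_equal(
    underlying_perm(decorated_perm(c(8, 11, 4, 12, 10, 15, 9, 14, 16))),
    c(8, 2, 4, 3, 1, 6, 9, 5, 7))
})

test_that("decorations_of enumerates 2^k decorations over the fixed points", {
  expect_length(decorations_of(1:2), 4L)
  d21 <- decorations_of(c(2, 1))
  expect_length(d21, 1L)
  expect_sigma(d21[[1]], "[2,3]")
  expect_length(decorations_of(c(1, 3, 2)), 2L)

  for (n in 1:5) {
    for (p in all_perms(n)) {
      k <- sum(p == seq_len(n))
      decs <- decorations_of(p)
      expect_length(decs, 2^k)
      expect_equal(anyDuplicated(vapply(decs, format_sigma, "")), 0L)
    }
  }
})

test_that("Markov projection reproduces the nine-state worked example", {
  expect_sigma(dperm_from_markov(chain9()), "[8,11,4,12,10,15,9,14,16]")
  expect_sigma(dperm_from_markov(chain9_transient2()),
               "[8,2,4,12,10,15,9,14,16]")
})

test_that("Markov projection labels the two-state cells", {
  expect_sigma(dperm_from_markov(kernel(diag(2))), "[3,4]")
  expect_sigma(dperm_from_markov(m2_kernel(1, 1)), "[2,3]")
  expect_sigma(dperm_from_markov(kernel(rbind(c(1, 0), c(.5, .5)))), "[3,2]")
  expect_sigma(dperm_from_markov(kernel(rbind(c(.5, .5), c(0, 1)))), "[1,4]")
})

test_that("Markov projection depends only on the support pattern", {
  set.seed(5)
  fixtures <- make_fixtures(4, count = 20, seed = 21,
                            family = "support-pattern")
  for (k in fixtures) {
    sig <- format_sigma(dperm_from_markov(k))
    m <- unclass(k)
    pos <- m > 0
    m[pos] <- m[pos] + runif(sum(pos))  # perturb positive entries only
    m <- m / rowSums(m)
    expect_equal(format_sigma(dperm_from_markov(kernel(m))), sig)
  }
})

test_that("Markov projection always yields a valid decorated permutation", {
  for (n in 2:7) {
    fixtures <- c(
      make_fixtures(n, count = 40, seed = 300 + n, family = "support-pattern"),
      make_fixtures(n, count = min(20L, n^n), seed = 400 + n,
                    family = "deterministic"),
      make_fixtures(n, count = 12, seed = 500 + n, family = "dirichlet")
    )
    for (k in fixtures) {
      sig <- dperm_from_markov(k)          # constructor validates
      expect_s3_class(sig, "decorated_perm")
      expect_equal(sig$n, n)
    }
  }
})

test_that("recurrent permutation chains map each class onto itself", {
  for (k in make_fixtures(6, count = 30, seed = 77, family = "deterministic")) {
    cs <- communicating_classes(k)
    u <- underlying_perm(dperm_from_markov(k))
    for (i in which(cs$recurrent)) {
      cl <- cs$classes[[i]]
      expect_setequal(u[cl], cl)
    }
  }
})

test_that("graph projection follows the isolated / self-loop / SCC rules", {
  expect_sigma(dperm_from_graph(rbind(c(1, 2), c(2, 1)), n = 3), "[2,4,3]")
  expect_sigma(dperm_from_graph(rbind(c(1, 1)), n = 1), "[2]")
  # transient-like singleton with an outgoing link
  expect_sigma(dperm_from_graph(rbind(c(1, 2), c(2, 2))), "[1,4]")
  # isolated nodes only
  expect_sigma(dperm_from_graph(matrix(integer(), 0, 2), n = 2), "[1,2]")
})

test_that("graph projection of a support digraph matches the Markov projection", {
  fixtures <- c(
    make_fixtures(5, count = 25, seed = 61, family = "deterministic"),
    make_fixtures(4, count = 15, seed = 62, family = "dirichlet"),
    list(chain9(), chain9_transient2(), kernel(diag(3)))
  )
  for (k in fixtures) {
    edges <- which(unclass(k) > 0, arr.ind = TRUE)
    expect_equal(
      format_sigma(dperm_from_graph(unname(edges), n = nrow(k))),
      format_sigma(dperm_from_markov(k)))
  }
})

test_that("Grassmannian projection labels planes by column spans", {
  expect_sigma(dperm_from_grassmannian(diag(2)), "[3,4]")
  expect_sigma(dperm_from_grassmannian(matrix(c(1, 1), 1)), "[2,3]")
  expect_sigma(dperm_from_grassmannian(matrix(c(1, 0), 1)), "[3,2]")
  expect_error(dperm_from_grassmannian(rbind(c(1, 0), c(1, 0))), "full row rank")

  # brute-force check on a generic 2 x 4 matrix: spans recomputed directly
  set.seed(9)
  C <- matrix(rnorm(8), 2, 4)
  sig <- dperm_from_grassmannian(C)
  for (a in 1:4) {
    b <- sig$images[a]
    cols <- ((a:(b - 1)) %% 4) + 1  # residues of a+1..b
    S <- C[, cols, drop = FALSE]
    expect_equal(qr(cbind(S, C[, a]))$rank, qr(S)$rank)
    if (b > a + 1) {
      S0 <- C[, ((a:(b - 2)) %% 4) + 1, drop = FALSE]
      expect_gt(qr(cbind(S0, C[, a]))$rank, qr(S0)$rank)
    }
  }
})

test_that("bracket strings round-trip through parse and format", {
  for (txt in c("[8,11,4,12,10,15,9,14,16]", "[3,4]", "[2]", "[3,5,4,6,7]")) {
    expect_equal(format_sigma(parse_sigma(txt)), txt)
  }
  expect_error(parse_sigma("[1,1]"), "range violation")
  expect_error(parse_sigma("1,2"), "cannot parse")
  expect_error(parse_sigma("[a,b]"), "cannot parse")
})
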