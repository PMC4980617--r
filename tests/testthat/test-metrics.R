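# dense-eigensolver oracle for eigenvector centrality
oracle_evc <- function(g) {
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  e <- eigen(a, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v)
  v / max(v)
}

test_that("prevalence is the smoker fraction", {
  expect_equal(prevalence(rep(1L, 7)), 1)
  expect_equal(prevalence(c(1L, 0L, 1L, 0L)), 0.5)
  expect_equal(prevalence(c(rep(1L, 20), rep(0L, 180))), 0.10)
})

test_that("eigenvector centrality matches closed forms and the dense oracle", {
  expect_equal(eigenvector_centrality(igraph::make_full_graph(5)), rep(1, 5))
  star <- igraph::make_star(5, mode = "undirected")   # centre + 4 leaves
  expect_equal(eigenvector_centrality(star), c(1, rep(0.5, 4)),
               tolerance = 1e-8)
  # disconnected: K4 dominates a path of 2; minor component goes to ~0
  g <- igraph::make_full_graph(4) + igraph::make_ring(2)
  v <- eigenvector_centrality(g)
  expect_equal(v, oracle_evc(g), tolerance = 1e-6)
  expect_lt(max(v[5:6]), 1e-6)
})

test_that("eigenvector centrality is invariant under node relabelling", {
  set.seed(13)
  g <- igraph::sample_gnp(20, 0.25)
  v <- eigenvector_centrality(g)
  perm <- sample(20)
  gp <- igraph::permute(g, perm)
  vp <- eigenvector_centrality(gp)
  expect_equal(vp[perm], v, tolerance = 1e-8)
})

test_that("an edgeless graph yields zero centralities with a warning", {
  expect_warning(v <- eigenvector_centrality(
    igraph::make_empty_graph(4, directed = FALSE)), "edgeless")
  expect_equal(v, rep(0, 4))
})

test_that("conditional smoking probability matches hand counts and flags empty shells", {
  path <- igraph::graph_from_literal(A - B - C - D)
  s <- c(1L, 1L, 0L, 0L)           # smokers A, B
  # ordered pairs at d=1 with smoking alter: (B,A),(A,B),(C,B); egos smoke in 2
  expect_equal(conditional_smoking_probability(path, s, 1), 2 / 3)
  expect_equal(conditional_smoking_probability(path, rep(1L, 4), 1), 1)
  expect_equal(conditional_smoking_probability(path, rep(1L, 4), 3), 1)
  expect_true(is.na(conditional_smoking_probability(path, rep(0L, 4), 1)))
  expect_error(conditional_smoking_probability(path, s, 0), ">= 1")
})

test_that("pooled CP agrees with a brute-force ordered-pair enumeration", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    g <- igraph::sample_gnp(n, 0.45)
    s <- sample(0:1, n, replace = TRUE)
    dm <- igraph::distances(g)
    for (d in 1:3) {
      num <- 0L; den <- 0L
      for (i in seq_len(n)) for (j in seq_len(n))
        if (i != j && is.finite(dm[i, j]) && dm[i, j] == d && s[j] == 1L) {
          den <- den + 1L
          if (s[i] == 1L) num <- num + 1L
        }
      want <- if (den == 0) NA_real_ else num / den
      expect_equal(conditional_smoking_probability(g, s, d), want)
    }
  }
})

test_that("bootstrap intervals are nested, degenerate on constants, and near the t-interval", {
  expect_equal(unname(bootstrap_ci(rep(2.5, 8), 0.95, seed = 1)[1, ]),
               c(2.5, 2.5))
  set.seed(23)
  x <- rnorm(100)
  ci <- bootstrap_ci(x, level = c(0.95, 0.99), reps = 4000, seed = 2)
  expect_lte(ci["99%", "lower"], ci["95%", "lower"])
  expect_gte(ci["99%", "upper"], ci["95%", "upper"])
  tt <- t.test(x, conf.level = 0.95)$conf.int
  expect_equal(unname(ci["95%", ]), as.numeric(tt), tolerance = 0.03)
  expect_warning(bootstrap_ci(1.3), "degenerate")
})
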