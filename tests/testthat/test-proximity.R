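# independent naive implementation of the ranked reciprocal update:
# explicit per-agent lists, explicit mutual-membership double loop
oracle_contact_update <- function(cadj, iadj, P, q) {
  n <- nrow(P)
  lists <- vector("list", n)
  for (i in seq_len(n)) {
    u <- sort(union(which(cadj[i, ]), which(iadj[i, ])))
    if (length(u)) {
      u <- u[order(-P[i, u], u)]
      lists[[i]] <- u[seq_len(min(q[i], length(u)))]
    } else lists[[i]] <- integer(0)
  }
  out <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && (j %in% lists[[i]]) && (i %in% lists[[j]]))
      out[i, j] <- TRUE
  out
}

test_that("proximity matrix is the convex behaviour/background combination", {
  b <- matrix(c(0, 1, 0.2, 1, 0, 0.6, 0.2, 0.6, 0), 3, 3)
  s <- c(1L, 1L, 0L)
  expect_equal(proximity_matrix(b, s, alpha = 0), b)
  p <- proximity_matrix(b, s, alpha = 0.2)
  expect_equal(p[1, 2], 1.0)    # same behaviour, B = 1
  expect_equal(p[1, 3], 0.16)   # different behaviour, B = 0.2
  expect_identical(p, t(p))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("three mutually interacting agents resolve to the single reciprocal edge", {
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- 0.9
  P[1, 3] <- P[3, 1] <- 0.5
  P[2, 3] <- P[3, 2] <- 0.4
  full <- matrix(TRUE, 3, 3); diag(full) <- FALSE
  adj <- update_contact_network(matrix(FALSE, 3, 3), full, P, q = c(1, 1, 2))
  want <- matrix(FALSE, 3, 3); want[1, 2] <- want[2, 1] <- TRUE
  # agent 3 lists both others but is reciprocated by neither
  expect_identical(adj, want)
})

test_that("a contact disappears when either side drops the other from its list", {
  # 1-2 are contacts; 2 interacts with 3 whose proximity beats 1; q2 = 1
  cadj <- matrix(FALSE, 3, 3); cadj[1, 2] <- cadj[2, 1] <- TRUE
  iadj <- matrix(FALSE, 3, 3); iadj[2, 3] <- iadj[3, 2] <- TRUE
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- 0.5
  P[2, 3] <- P[3, 2] <- 0.9
  adj <- update_contact_network(cadj, iadj, P, q = c(3, 1, 3))
  expect_false(adj[1, 2])          # 1 dropped passively by 2
  expect_true(adj[2, 3])
})

test_that("no tie can form between agents that did not interact", {
  # high mutual proximity but never in each other's candidate set
  P <- matrix(0.9, 4, 4); diag(P) <- 0
  cadj <- matrix(FALSE, 4, 4); cadj[1, 2] <- cadj[2, 1] <- TRUE
  iadj <- matrix(FALSE, 4, 4)
  adj <- update_contact_network(cadj, iadj, P, q = rep(3, 4))
  expect_false(adj[3, 4])
  expect_true(adj[1, 2])           # surviving existing contact
})

test_that("updated degrees never exceed the degree preference and stay symmetric", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    P <- matrix(runif(n * n), n, n); P <- (P + t(P)) / 2; diag(P) <- 0
    cadj <- matrix(runif(n * n) < 0.3, n, n); cadj <- cadj | t(cadj)
    diag(cadj) <- FALSE
    iadj <- matrix(runif(n * n) < 0.4, n, n); iadj <- iadj | t(iadj)
    diag(iadj) <- FALSE
    q <- sample(1:(n - 1), n, replace = TRUE)
    adj <- update_contact_network(cadj, iadj, P, q)
    expect_identical(adj, t(adj))
    expect_true(all(rowSums(adj) <= q))
  }
})

test_that("the vectorised update agrees with the brute-force ranked-list oracle", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    P <- matrix(runif(n * n), n, n); P <- (P + t(P)) / 2; diag(P) <- 0
    cadj <- matrix(runif(n * n) < 0.35, n, n); cadj <- cadj | t(cadj)
    diag(cadj) <- FALSE
    iadj <- matrix(runif(n * n) < 0.35, n, n); iadj <- iadj | t(iadj)
    diag(iadj) <- FALSE
    q <- sample(1:(n - 1), n, replace = TRUE)
    expect_identical(update_contact_network(cadj, iadj, P, q),
                     oracle_contact_update(cadj, iadj, P, q))
  }
})

test_that("with static states and no outside interactions the network is a fixed point", {
  set.seed(41)
  n <- 12
  b <- matrix(runif(n * n, 0.2, 1), n, n); b <- (b + t(b)) / 2; diag(b) <- 0
  s <- rep(c(0L, 1L), n / 2)
  P <- proximity_matrix(b, s)
  q <- rep(4L, n)
  adj <- initial_contact_network(P, q)
  again <- update_contact_network(adj, adj, P, q)   # interactions = contacts
  expect_identical(adj, again)
})

test_that("igraph input round-trips through the contact update", {
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- 0.9
  P[2, 3] <- P[3, 2] <- 0.8
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  full <- igraph::make_full_graph(3)
  g1 <- update_contact_network(g0, full, P, q = c(1, 2, 1))
  expect_s3_class(g1, "igraph")
  expect_equal(igraph::ecount(g1), 2)
})
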