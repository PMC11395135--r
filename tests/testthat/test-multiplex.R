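test_that("multiplex fusion follows the node policy", {
  g1 <- layer_graph(data.frame(from = c("A", "B"), to = c("B", "C")),
                    name = "l1")
  g2 <- layer_graph(data.frame(from = c("B", "C"), to = c("C", "D")),
                    name = "l2")
  mi <- build_multiplex(list(g1, g2))
  expect_equal(mi$node_index, c("B", "C"))
  expect_equal(mi$L, 2)
  # restriction drops edges with endpoints outside the common set
  expect_equal(n_edges(mi$layers[[1]]), 1)

  mu <- build_multiplex(list(g1, g2), node_policy = "union")
  expect_equal(mu$node_index, c("A", "B", "C", "D"))
  # A isolated in layer 2, D isolated in layer 1
  expect_false("A" %in% unlist(mu$layers[[2]]$edges[, 1:2]))
  expect_false("D" %in% unlist(mu$layers[[1]]$edges[, 1:2]))

  single <- build_multiplex(list(g1))
  expect_equal(single$node_index, g1$nodes)
  expect_equal(single$L, 1)

  disjoint <- layer_graph(data.frame(from = "X", to = "Y"))
  expect_error(build_multiplex(list(g1, disjoint)), "union")
})

test_that("hand-computed 4x4 supra operator for twin single-edge layers", {
  g <- layer_graph(data.frame(from = "A", to = "B"))
  mx <- build_multiplex(list(layer_graph(g$edges, name = "x"),
                             layer_graph(g$edges, name = "y")))
  st <- build_supra_transition(mx, delta = 0.5)
  M <- as.matrix(st$matrix)
  # supra order: (x,A), (x,B), (y,A), (y,B); column = from, row = to
  expected <- matrix(c(
    0, 0.5, 0.5, 0,
    0.5, 0, 0, 0.5,
    0.5, 0, 0, 0.5,
    0, 0.5, 0.5, 0
  ), nrow = 4, byrow = FALSE)
  expect_equal(unname(M), expected)
  expect_equal(unname(Matrix::colSums(st$matrix)), rep(1, 4))
})

test_that("single layer gives the column-normalised adjacency", {
  set.seed(1)
  g <- random_connected_layer(12)
  mx <- build_multiplex(list(g))
  st <- build_supra_transition(mx, delta = 0.9)  # delta forced to 0 at L = 1
  expect_equal(st$delta, 0)
  A <- layer_adjacency(g, mx$node_index)
  expected <- t(t(as.matrix(A)) / Matrix::colSums(A))
  expect_equal(unname(as.matrix(st$matrix)), unname(expected))
})

test_that("columns are stochastic across random specs including isolation", {
  set.seed(7)
  for (rep in 1:20) {
    L <- sample(1:3, 1)
    n <- sample(5:40, 1)
    mx <- random_multiplex(n, L, p = runif(1, 0.05, 0.3))
    st <- build_supra_transition(mx, delta = runif(1))
    expect_equal(unname(Matrix::colSums(st$matrix)), rep(1, L * n),
                 tolerance = 1e-12)
  }
  # union policy with nodes missing from some layers
  g1 <- layer_graph(data.frame(from = c("A", "B"), to = c("B", "C")),
                    name = "l1")
  g2 <- layer_graph(data.frame(from = "C", to = "D"), name = "l2")
  mu <- build_multiplex(list(g1, g2), node_policy = "union")
  st <- build_supra_transition(mu, delta = 0.5)
  expect_equal(unname(Matrix::colSums(st$matrix)), rep(1, 8))
  # A is isolated in layer 2: its layer-2 column sends everything to layer 1
  i_A2 <- 4 + match("A", mu$node_index)
  expect_equal(as.numeric(st$matrix[match("A", mu$node_index), i_A2]), 1)
})

test_that("nodes isolated in every layer get self-loops", {
  ids <- c("A", "B", "Z")
  g1 <- layer_graph(data.frame(from = "A", to = "B"), nodes = ids, name = "1")
  g2 <- layer_graph(data.frame(from = "A", to = "B"), nodes = ids, name = "2")
  mx <- build_multiplex(list(g1, g2))
  st <- suppressMessages(build_supra_transition(mx, delta = 0.5))
  iz <- match("Z", mx$node_index)
  expect_equal(as.numeric(st$matrix[iz, iz]), 1)
  expect_equal(as.numeric(st$matrix[3 + iz, 3 + iz]), 1)
  expect_equal(unname(Matrix::colSums(st$matrix)), rep(1, 6))
})

test_that("delta = 0 gives a block-diagonal supra operator", {
  set.seed(11)
  mx <- random_multiplex(15, 3, p = 0.2)
  st <- build_supra_transition(mx, delta = 0)
  M <- st$matrix
  n <- mx$n
  for (x in 1:3) for (y in 1:3) {
    if (x != y) {
      blk <- M[(y - 1) * n + 1:n, (x - 1) * n + 1:n]
      expect_equal(sum(abs(blk)), 0)
    }
  }
  expect_equal(unname(Matrix::colSums(M)), rep(1, 3 * n))
})

test_that("walk scores are equivariant under node relabelling", {
  set.seed(21)
  mx <- random_multiplex(20, 2, p = 0.2)
  ids <- mx$node_index
  perm <- setNames(sample(node_ids(20, "z")), ids)
  relabelled <- build_multiplex(lapply(mx$layers, function(g) {
    e <- g$edges
    e$from <- unname(perm[e$from])
    e$to <- unname(perm[e$to])
    layer_graph(e, nodes = unname(perm[g$nodes]), name = g$name)
  }))
  seeds <- ids[1:3]
  run <- function(m, s) {
    N <- build_supra_transition(m, 0.5)
    pr <- restart_profile(m)
    rwmrp(m, N, pr, s)$scores
  }
  s1 <- run(mx, seeds)
  s2 <- run(relabelled, unname(perm[seeds]))
  expect_equal(unname(s2[perm[ids]]), unname(s1[ids]), tolerance = 1e-12)
})

test_that("multiplex round-trips through TSV layers plus manifest", {
  set.seed(3)
  mx <- random_multiplex(12, 2, p = 0.25)
  dir <- withr::local_tempdir()
  write_multiplex(mx, dir)
  back <- read_multiplex(dir)
  expect_equal(back$node_index, mx$node_index)
  expect_equal(back$L, mx$L)
  for (i in 1:2) expect_equal(back$layers[[i]]$edges, mx$layers[[i]]$edges)
})
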