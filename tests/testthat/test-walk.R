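test_that("initial distribution splits tau mass uniformly over seeds", {
  set.seed(4)
  mx <- random_multiplex(4, 2, p = 0.8)
  s <- mx$node_index[1]
  p0 <- initial_distribution(mx, s)
  expect_equal(sum(p0), 1)
  expect_equal(unname(p0[c(1, 5)]), c(0.5, 0.5))

  single <- build_multiplex(list(mx$layers[[1]]))
  p1 <- initial_distribution(single, mx$node_index[1:2])
  expect_equal(sort(unname(p1[p1 > 0])), c(0.5, 0.5))

  pe <- initial_distribution(mx, s, tau = c(1, 0))
  expect_equal(sum(pe[1:4]), 1)
  expect_equal(sum(pe[5:8]), 0)

  expect_error(initial_distribution(mx, "nope"), "not in the multiplex")
  expect_error(initial_distribution(mx, s, tau = c(0.5, 0.4)), "sum to 1")
})

test_that("converged scores on the 2-node path match the closed form", {
  g <- layer_graph(data.frame(from = "A", to = "B"))
  mx <- build_multiplex(list(g))
  N <- build_supra_transition(mx)
  prof <- restart_profile(mx, mode = "uniform", r_uniform = 0.7)
  sv <- rwmrp(mx, N, prof, "A", stop_rule = "tolerance", max_iter = 1000,
              tol = 1e-14)
  # fixed point of p_A = r + (1-r) p_B, p_B = (1-r) p_A
  expect_equal(unname(sv$scores[c("A", "B")]), c(1 / 1.3, 0.3 / 1.3),
               tolerance = 1e-10)
})

test_that("uniform-profile walker equals the textbook RWR oracle", {
  set.seed(13)
  for (rep in 1:25) {
    L <- sample(1:3, 1)
    n <- sample(5:30, 1)
    mx <- random_multiplex(n, L, p = 0.25)
    r <- runif(1, 0.1, 0.9)
    seeds <- sample(mx$node_index, sample(1:3, 1))
    N <- build_supra_transition(mx, delta = 0.5)
    prof <- restart_profile(mx, mode = "uniform", r_uniform = r)
    sv <- rwmrp(mx, N, prof, seeds, max_iter = 20)
    oracle <- rwr_oracle(N$matrix, unname(initial_distribution(mx, seeds)),
                         r, 20)
    expect_lt(max(abs(unname(sv$supra) - oracle)), 1e-10)
  }
})

test_that("walker conserves probability mass with node-specific restarts", {
  set.seed(17)
  for (rep in 1:20) {
    mx <- random_multiplex(sample(5:40, 1), sample(1:3, 1), p = 0.2)
    prof <- random_profile(mx)
    N <- build_supra_transition(mx, delta = runif(1))
    seeds <- sample(mx$node_index, 2)
    for (iters in c(1, 7, 20)) {
      sv <- rwmrp(mx, N, prof, seeds, max_iter = iters)
      expect_equal(sum(sv$supra), 1, tolerance = 1e-10)
      expect_equal(sum(sv$scores), 1, tolerance = 1e-10)
    }
  }
})

test_that("restart probability 1 everywhere pins the walker to the seeds", {
  set.seed(19)
  mx <- random_multiplex(10, 2, p = 0.3)
  prof <- rwmrp:::new_restart_profile(
    setNames(rep(1, 20), supra_names(mx)), "centrality"
  )
  N <- build_supra_transition(mx)
  seeds <- mx$node_index[1:2]
  sv <- rwmrp(mx, N, prof, seeds, max_iter = 20)
  p0 <- initial_distribution(mx, seeds)
  agg0 <- tapply(unname(p0), rep(mx$node_index, 2), sum)[mx$node_index]
  expect_equal(unname(sv$scores), as.numeric(agg0), tolerance = 1e-12)
})

test_that("a 1-layer multiplex reduces to the single-layer walk", {
  set.seed(23)
  g <- random_connected_layer(15)
  mx1 <- build_multiplex(list(g))
  run <- function(m) {
    N <- build_supra_transition(m, delta = 0.5)
    prof <- restart_profile(m)
    rwmrp(m, N, prof, m$node_index[1:2], max_iter = 20)$scores
  }
  # same layer wrapped twice under different names must give identical scores
  g2 <- layer_graph(g$edges, nodes = g$nodes, name = "other")
  expect_equal(unname(run(mx1)), unname(run(build_multiplex(list(g2)))))
})

test_that("tolerance stop reaches a fixed point of the update", {
  set.seed(29)
  mx <- random_multiplex(20, 2, p = 0.2)
  prof <- random_profile(mx)
  N <- build_supra_transition(mx)
  sv <- rwmrp(mx, N, prof, mx$node_index[1:3], stop_rule = "tolerance",
              tol = 1e-12, max_iter = 5000)
  p <- unname(sv$supra)
  p0 <- unname(initial_distribution(mx, mx$node_index[1:3]))
  q <- as.numeric(N$matrix %*% p)
  z <- sum(unname(prof$restart) * q)
  p_next <- unname(prof$move) * q + z * p0
  expect_lt(sum(abs(p_next - p)), 1e-11)
})

test_that("paper-literal z-mode stays a probability distribution and is close
           to the conserving mode at the fixed point", {
  set.seed(31)
  mx <- random_multiplex(15, 2, p = 0.25)
  prof <- random_profile(mx)
  N <- build_supra_transition(mx)
  seeds <- mx$node_index[1:2]
  lit <- rwmrp(mx, N, prof, seeds, max_iter = 50, z_mode = "paper_literal")
  expect_equal(sum(lit$supra), 1, tolerance = 1e-12)
  con <- rwmrp(mx, N, prof, seeds, max_iter = 50)
  # same seeds, same operator: the two conventions rank genes very similarly
  expect_gt(cor(unname(lit$scores), unname(con$scores), method = "spearman"),
            0.9)
})

test_that("seed mass dominates under strong restarts", {
  set.seed(37)
  wins <- 0
  for (rep in 1:10) {
    mx <- random_multiplex(30, 2, p = 0.15)
    prof <- random_profile(mx, lo = 0.5, hi = 0.95)
    N <- build_supra_transition(mx)
    seeds <- sample(mx$node_index, 3)
    sv <- rwmrp(mx, N, prof, seeds, max_iter = 20)
    others <- sample(setdiff(mx$node_index, seeds), 3)
    if (sum(sv$scores[seeds]) > sum(sv$scores[others])) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("gene ranking sorts, excludes seeds, and gives ties the worst rank", {
  s <- c(A = 0.5, B = 0.3, C = 0.2)
  rk <- rank_genes(s)
  expect_equal(rk$gene, c("A", "B", "C"))
  expect_equal(rk$rank, 1:3)

  tied <- c(A = 0.5, B = 0.25, C = 0.25)
  rkt <- rank_genes(tied)
  expect_equal(rkt$rank[rkt$gene %in% c("B", "C")], c(3L, 3L))

  rke <- rank_genes(s, seeds = "A")
  expect_false("A" %in% rke$gene)
  expect_equal(rke$rank, 1:2)
})
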