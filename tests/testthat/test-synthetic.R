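test_that("attachment background has the forced edge count and connectivity", {
  sim <- generate_multiplex(synthetic_spec(n = 50, L = 1, module_size = 0,
                                           attachment_m = 2,
                                           generator_seed = 1))
  g <- sim$multiplex$layers[[1]]
  expect_equal(n_edges(g), 2 * 48)  # m edges from each of the n - m added nodes
  expect_equal(length(sim$module), 0)
  # connectivity: every node reachable (checked via the supra operator of the
  # single layer having no all-zero rows/cols and a BFS over edges)
  adj <- split(c(g$edges$to, g$edges$from), c(g$edges$from, g$edges$to))
  seen <- g$nodes[1]
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  expect_setequal(seen, g$nodes)
})

test_that("p_in = 1 plants the complete module in every layer", {
  sim <- generate_multiplex(synthetic_spec(n = 30, L = 2, module_size = 10,
                                           p_in = 1, generator_seed = 2))
  pairs <- t(utils::combn(sort(sim$module), 2))
  for (g in sim$multiplex$layers) {
    key <- paste(g$edges$from, g$edges$to)
    expect_true(all(paste(pairs[, 1], pairs[, 2]) %in% key))
  }
})

test_that("generation is a pure function of the spec", {
  spec <- synthetic_spec(n = 40, L = 3, module_size = 5, generator_seed = 11)
  a <- generate_multiplex(spec)
  b <- generate_multiplex(spec)
  expect_identical(a$module, b$module)
  for (i in 1:3) {
    expect_identical(a$multiplex$layers[[i]]$edges,
                     b$multiplex$layers[[i]]$edges)
  }
  # a different seed changes the topology
  c <- generate_multiplex(synthetic_spec(n = 40, L = 3, module_size = 5,
                                         generator_seed = 12))
  expect_false(identical(a$multiplex$layers[[1]]$edges,
                         c$multiplex$layers[[1]]$edges))
  # the caller's RNG stream is left untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_multiplex(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("background degree distributions are heavy-tailed", {
  for (seed in 1:10) {
    sim <- generate_multiplex(synthetic_spec(n = 200, L = 1, module_size = 0,
                                             attachment_m = 2,
                                             generator_seed = seed))
    g <- sim$multiplex$layers[[1]]
    deg <- table(c(g$edges$from, g$edges$to))
    expect_gte(max(deg), 3 * stats::median(deg))
  }
})

test_that("layer overlap copies edges between consecutive layers", {
  spec_hi <- synthetic_spec(n = 80, L = 2, module_size = 0,
                            layer_overlap = 1, generator_seed = 5)
  sim <- generate_multiplex(spec_hi)
  e1 <- paste(sim$multiplex$layers[[1]]$edges$from,
              sim$multiplex$layers[[1]]$edges$to)
  e2 <- paste(sim$multiplex$layers[[2]]$edges$from,
              sim$multiplex$layers[[2]]$edges$to)
  expect_true(all(e1 %in% e2))  # overlap 1: layer 2 contains all of layer 1

  spec_lo <- synthetic_spec(n = 80, L = 2, module_size = 0,
                            layer_overlap = 0, generator_seed = 5)
  sim0 <- generate_multiplex(spec_lo)
  e1 <- paste(sim0$multiplex$layers[[1]]$edges$from,
              sim0$multiplex$layers[[1]]$edges$to)
  e2 <- paste(sim0$multiplex$layers[[2]]$edges$from,
              sim0$multiplex$layers[[2]]$edges$to)
  expect_lt(mean(e1 %in% e2), 0.5)  # only chance coincidences
})

test_that("spec validation rejects impossible parameters", {
  expect_error(synthetic_spec(n = 10, module_size = 10), "module_size")
  expect_error(synthetic_spec(p_in = 0), "p_in")
  expect_error(synthetic_spec(attachment_m = 0), "attachment_m")
})

test_that("score tables separate module from background genes", {
  conform <- 0
  for (seed in 1:10) {
    sim <- generate_multiplex(synthetic_spec(n = 40, L = 1, module_size = 5,
                                             generator_seed = seed))
    tab <- generate_score_table(sim$module, sim$multiplex$node_index,
                                signal = 0.95, noise = 0.2,
                                generator_seed = seed)
    cand <- select_candidates(sim$multiplex$node_index, sim$module, tab)
    module_in <- mean(sim$module %in% cand$candidate)
    background <- setdiff(sim$multiplex$node_index, sim$module)
    background_in <- mean(background %in% cand$candidate)
    # "conform": module genes pass the default filter on average,
    # background genes do not
    if (module_in > 0.5 && background_in < 0.5) conform <- conform + 1
  }
  expect_gte(conform, 9)

  expect_error(generate_score_table("a", c("a", "b"), signal = 0.5,
                                    noise = 0.5), "exceed")
  empty <- generate_score_table(character(0), c("a", "b"))
  expect_equal(nrow(empty), 0)
})
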