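# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code under fixed seeds; no stored data files.

node_ids <- function(n, prefix = "n") sprintf("%s%03d", prefix, seq_len(n))

# Erdos-Renyi-style random layer over a fixed node universe.
random_layer <- function(n, p = 0.15, ids = node_ids(n), weighted = FALSE,
                         name = "L") {
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  w <- if (weighted) stats::runif(sum(keep), 0.1, 1) else 1
  layer_graph(
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2], weight = w,
               stringsAsFactors = FALSE),
    nodes = ids, name = name
  )
}

# Random connected layer: spanning tree plus extra random edges.
random_connected_layer <- function(n, extra = n, ids = node_ids(n),
                                   name = "L") {
  from <- ids[vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))]
  tree <- data.frame(from = from, to = ids[2:n], weight = 1,
                     stringsAsFactors = FALSE)
  if (extra > 0) {
    more <- data.frame(from = sample(ids, extra, replace = TRUE),
                       to = sample(ids, extra, replace = TRUE),
                       weight = rep(1, extra), stringsAsFactors = FALSE)
    tree <- rbind(tree, more[more$from != more$to, , drop = FALSE])
  }
  layer_graph(tree, nodes = ids, name = name)
}

# Random multiplex over a shared node universe.
random_multiplex <- function(n, L, p = 0.15) {
  ids <- node_ids(n)
  build_multiplex(lapply(seq_len(L), function(x) {
    random_layer(n, p, ids = ids, name = paste0("L", x))
  }))
}

# Random node-specific restart profile with entries strictly inside (0, 1).
random_profile <- function(mx, lo = 0.05, hi = 0.95) {
  r <- stats::runif(mx$L * mx$n, lo, hi)
  rwmrp:::new_restart_profile(stats::setNames(r, supra_names(mx)),
                              "centrality", lo, hi)
}

# Independent textbook RWR oracle on a supra operator: p <- (1-r) M p + r p0.
rwr_oracle <- function(M, p0, r, iters) {
  p <- p0
  for (t in seq_len(iters)) p <- (1 - r) * as.numeric(M %*% p) + r * p0
  p
}

# Dense dominant-eigenvector oracle for centrality tests.
dense_centrality_oracle <- function(g) {
  A <- as.matrix(layer_adjacency(g))
  es <- eigen(A, symmetric = TRUE)
  v <- es$vectors[, 1]
  if (sum(v) < 0) v <- -v
  list(values = stats::setNames(v / max(v), g$nodes),
       lambda = es$values[1])
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Brute-force association filter: literal enumeration over potential genes.
brute_force_candidates <- function(potential, known, table,
                                   min_partners, min_score) {
  keep <- character(0)
  npart <- integer(0)
  for (g in potential) {
    cnt <- 0L
    for (k in known) {
      hit <- table$score[table$potential_gene == g & table$known_gene == k]
      if (length(hit) == 1 && hit >= min_score) cnt <- cnt + 1L
    }
    if (cnt >= min_partners) {
      keep <- c(keep, g)
      npart <- c(npart, cnt)
    }
  }
  data.frame(candidate = keep, n_partners = npart, stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
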