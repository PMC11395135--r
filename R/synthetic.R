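#' Specification for a synthetic multiplex benchmark
#'
#' Describes a multi-layer network with scale-free background layers and a
#' planted, densely interconnected "response module" standing in for a set of
#' known stress-responsive genes. Every output of the generator is a pure
#' function of this spec, including `generator_seed`.
#'
#' @param n nodes per layer (shared node universe).
#' @param L number of layers.
#' @param module_size planted-module gene count, `< n` (0 for no module).
#' @param p_in within-module edge probability per layer, in (0, 1\].
#' @param attachment_m edges added per new node in the preferential-attachment
#'   background, `>= 1`.
#' @param layer_overlap probability that an edge of layer `x - 1` is copied
#'   into layer `x`, giving partially overlapping layer topologies.
#' @param generator_seed integer RNG seed.
#' @return An object of class `synthetic_spec` (validated list).
#' @export
synthetic_spec <- function(n = 200, L = 3, module_size = 20, p_in = 0.3,
                           attachment_m = 2, layer_overlap = 0.3,
                           generator_seed = 1) {
  if (module_size >= n) stop("module_size must be < n")
  if (module_size < 0) stop("module_size must be >= 0")
  if (p_in <= 0 || p_in > 1) stop("p_in must be in (0, 1]")
  if (attachment_m < 1) stop("attachment_m must be >= 1")
  if (layer_overlap < 0 || layer_overlap > 1) {
    stop("layer_overlap must be in [0, 1]")
  }
  if (n < max(2, attachment_m + 1)) stop("n too small for attachment_m")
  structure(
    list(n = as.integer(n), L = as.integer(L),
         module_size = as.integer(module_size), p_in = p_in,
         attachment_m = as.integer(attachment_m),
         layer_overlap = layer_overlap,
         generator_seed = as.integer(generator_seed)),
    class = "synthetic_spec"
  )
}

# Barabasi-Albert-style background: the first m nodes start edgeless; each of
# the remaining n - m nodes attaches to m distinct existing nodes drawn
# proportionally to degree (uniformly while all degrees are zero), giving
# exactly m * (n - m) edges and a heavy-tailed degree distribution.
pa_background <- function(node_ids, m) {
  n <- length(node_ids)
  deg <- numeric(n)
  from <- integer(m * (n - m))
  to <- integer(m * (n - m))
  k <- 0L
  for (v in (m + 1):n) {
    existing <- seq_len(v - 1)
    w <- deg[existing]
    if (sum(w) == 0) w <- rep(1, length(existing))
    targets <- sample(existing, m, prob = w)
    from[k + seq_len(m)] <- v
    to[k + seq_len(m)] <- targets
    k <- k + m
    deg[v] <- deg[v] + m
    deg[targets] <- deg[targets] + 1
  }
  data.frame(from = node_ids[from], to = node_ids[to], weight = 1,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multiplex with a planted response module
#'
#' Each layer is a preferential-attachment (scale-free) background over the
#' full node set, plus dense module edges: every pair of planted-module genes
#' is connected independently with probability `p_in` per layer. Consecutive
#' layers additionally share topology: each edge of layer `x - 1` is copied
#' into layer `x` with probability `layer_overlap`. The planted module is
#' returned as ground truth for recovery benchmarks.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `multiplex` (a `multiplex_network`) and `module`
#'   (character vector of planted-module genes).
#' @examples
#' sim <- generate_multiplex(synthetic_spec(n = 60, L = 2, module_size = 8))
#' sim$multiplex
#' @export
generate_multiplex <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$generator_seed)

  ids <- sprintf("g%0*d", nchar(spec$n), seq_len(spec$n))
  module <- if (spec$module_size > 0) {
    sort(sample(ids, spec$module_size))
  } else {
    character(0)
  }
  module_pairs <- if (length(module) >= 2) t(utils::combn(module, 2)) else NULL

  layers <- vector("list", spec$L)
  prev_edges <- NULL
  for (x in seq_len(spec$L)) {
    e <- pa_background(ids, spec$attachment_m)
    if (!is.null(module_pairs)) {
      keep <- stats::runif(nrow(module_pairs)) <= spec$p_in
      if (any(keep)) {
        e <- rbind(e, data.frame(from = module_pairs[keep, 1],
                                 to = module_pairs[keep, 2], weight = 1,
                                 stringsAsFactors = FALSE))
      }
    }
    if (!is.null(prev_edges) && spec$layer_overlap > 0 &&
        nrow(prev_edges) > 0) {
      reuse <- stats::runif(nrow(prev_edges)) <= spec$layer_overlap
      if (any(reuse)) e <- rbind(e, prev_edges[reuse, , drop = FALSE])
    }
    g <- layer_graph(e, nodes = ids, name = paste0("layer", x))
    layers[[x]] <- g
    prev_edges <- g$edges
  }
  list(
    multiplex = build_multiplex(layers, node_policy = "intersection"),
    module = module
  )
}

#' Generate an interaction-score table correlated with module membership
#'
#' Emulates a database of pairwise interaction scores: pairs where the
#' potential gene belongs to the planted module draw from a clipped
#' `Normal(signal, sd)`, all other pairs from a clipped `Normal(noise, sd)`.
#' Known genes are the module genes; every (potential, known) pair with
#' distinct genes gets a row.
#'
#' @param planted_module character vector of module (known) genes.
#' @param all_genes character vector of all genes (potential genes).
#' @param signal mean score for module pairs, in \[0, 1\]; must exceed
#'   `noise`.
#' @param noise mean score for background pairs.
#' @param sd normal standard deviation before clipping to \[0, 1\].
#' @param generator_seed integer RNG seed.
#' @return A [score_table()].
#' @export
generate_score_table <- function(planted_module, all_genes,
                                 signal = 0.95, noise = 0.2, sd = 0.05,
                                 generator_seed = 1) {
  if (signal <= noise) stop("signal must exceed noise")
  if (signal > 1 || signal < 0 || noise < 0) stop("means must be in [0, 1]")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(generator_seed)

  known <- sort(unique(as.character(planted_module)))
  potential <- sort(unique(as.character(all_genes)))
  if (length(known) == 0) {
    return(score_table(data.frame(potential_gene = character(),
                                  known_gene = character(),
                                  score = numeric())))
  }
  grid <- expand.grid(potential_gene = potential, known_gene = known,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$potential_gene != grid$known_gene, , drop = FALSE]
  mu <- ifelse(grid$potential_gene %in% known, signal, noise)
  s <- stats::rnorm(nrow(grid), mean = mu, sd = sd)
  grid$score <- pmin(1, pmax(0, s))
  rownames(grid) <- NULL
  score_table(grid)
}

#' Write a complete self-contained demo dataset
#'
#' Generates a synthetic multiplex, known-gene list and score table, and
#' writes them as plain text: per-layer TSV edge lists plus `manifest.json`
#' (see [write_multiplex()]), `known_genes.txt`, and `score_table.tsv`.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if absent).
#' @param signal,noise score-table means, see [generate_score_table()].
#' @return `dir`, invisibly.
#' @export
write_demo_dataset <- function(spec, dir, signal = 0.95, noise = 0.2) {
  sim <- generate_multiplex(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_multiplex(sim$multiplex, dir)
  writeLines(sim$module, file.path(dir, "known_genes.txt"))
  tab <- generate_score_table(sim$module, sim$multiplex$node_index,
                              signal = signal, noise = noise,
                              generator_seed = spec$generator_seed)
  utils::write.table(tab, file.path(dir, "score_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
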