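#' Fuse layers into a multiplex network
#'
#' A multiplex network is a set of layers sharing one node set; a node exists
#' in every layer (possibly isolated in some) and inter-layer edges connect a
#' node only to its own counterpart in other layers. The shared node set is
#' either the intersection of the layers' node sets (the default: only genes
#' observed in every evidence source are retained) or their union (layers are
#' padded with isolated nodes).
#'
#' @param layers list of [layer_graph()] objects, at least one.
#' @param node_policy `"intersection"` (default) or `"union"`.
#' @return An object of class `multiplex_network`: list with `layers`
#'   (restricted/padded layer_graphs), `node_index` (sorted common node
#'   vector), `L` and `n`.
#' @export
build_multiplex <- function(layers, node_policy = c("intersection", "union")) {
  node_policy <- match.arg(node_policy)
  if (length(layers) < 1) stop("need at least one layer")
  lapply(layers, function(g) stopifnot(inherits(g, "layer_graph")))

  node_sets <- lapply(layers, function(g) g$nodes)
  node_index <- if (node_policy == "intersection") {
    Reduce(intersect, node_sets)
  } else {
    unique(unlist(node_sets))
  }
  if (node_policy == "intersection" && length(node_index) == 0) {
    stop("layers share no common nodes; consider node_policy = \"union\"")
  }
  node_index <- sort(node_index)
  if (length(node_index) < 2) stop("multiplex needs at least 2 shared nodes")

  restricted <- lapply(layers, function(g) {
    e <- g$edges
    e <- e[e$from %in% node_index & e$to %in% node_index, , drop = FALSE]
    layer_graph(e, nodes = node_index, name = g$name)
  })
  nm <- vapply(restricted, function(g) g$name, character(1))
  if (anyDuplicated(nm)) {
    nm <- make.unique(nm)
    for (i in seq_along(restricted)) restricted[[i]]$name <- nm[i]
  }

  structure(
    list(layers = restricted, node_index = node_index,
         L = length(restricted), n = length(node_index),
         node_policy = node_policy),
    class = "multiplex_network"
  )
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat("<multiplex_network> L =", x$L, "layers over n =", x$n, "shared nodes\n")
  for (g in x$layers) {
    cat("  ", g$name, ": ", nrow(g$edges), " edges\n", sep = "")
  }
  invisible(x)
}

#' Sparse adjacency matrix of a layer over a fixed node ordering
#'
#' @param g a [layer_graph()].
#' @param node_index character vector fixing row/column order; defaults to the
#'   layer's own (sorted) node set.
#' @return Symmetric sparse `dgCMatrix` of edge weights.
#' @export
layer_adjacency <- function(g, node_index = g$nodes) {
  n <- length(node_index)
  i <- match(g$edges$from, node_index)
  j <- match(g$edges$to, node_index)
  keep <- !is.na(i) & !is.na(j)
  A <- Matrix::sparseMatrix(
    i = c(i[keep], j[keep]), j = c(j[keep], i[keep]),
    x = rep(g$edges$weight[keep], 2),
    dims = c(n, n), dimnames = list(node_index, node_index)
  )
  methods::as(A, "CsparseMatrix")
}

#' Supra index of (layer, node) pairs
#'
#' The supra-vector convention used throughout: entry for node `i` (1-based
#' position in `node_index`) in layer `x` sits at `(x - 1) * n + i`.
#'
#' @param mx a `multiplex_network`.
#' @return Character vector of length `L * n` labelling supra entries as
#'   `"<layer>::<node>"`, in supra order.
#' @export
supra_names <- function(mx) {
  unlist(lapply(mx$layers, function(g) paste0(g$name, "::", mx$node_index)))
}

#' Build the column-stochastic supra-transition operator
#'
#' Encodes one step of the walker on the multiplex: from node `i` in layer
#' `x`, it moves to a within-layer neighbour with total probability
#' `1 - delta` (split proportionally to edge weights) and jumps to the same
#' node in one of the other `L - 1` layers with total probability `delta`
#' (split equally). Nodes isolated in layer `x` but connected elsewhere send
#' all their mass to their other-layer counterparts; nodes isolated in every
#' layer get a self-loop so columns stay stochastic (these are flagged with a
#' message). For a single layer, `delta` is forced to 0.
#'
#' @param mx a `multiplex_network` from [build_multiplex()].
#' @param delta inter-layer jump probability in \[0, 1\]; default 0.5, the
#'   standard multiplex random-walk convention.
#' @return An object of class `supra_transition`: list with `matrix` (sparse
#'   `(L n) x (L n)` column-stochastic operator), `delta`, `L`, `n`,
#'   `node_index`.
#' @export
build_supra_transition <- function(mx, delta = 0.5) {
  stopifnot(inherits(mx, "multiplex_network"))
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0 || delta > 1) {
    stop("delta must be a single number in [0, 1]")
  }
  L <- mx$L
  n <- mx$n
  if (L == 1) delta <- 0

  adj <- lapply(mx$layers, layer_adjacency, node_index = mx$node_index)
  deg <- vapply(adj, Matrix::colSums, numeric(n))  # n x L weighted degrees
  deg <- matrix(deg, nrow = n)
  isolated_everywhere <- rowSums(deg > 0) == 0
  if (any(isolated_everywhere)) {
    message("build_supra_transition: ", sum(isolated_everywhere),
            " node(s) isolated in every layer; given self-loops")
  }

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (x in seq_len(L)) {
    off <- (x - 1L) * n
    A <- adj[[x]]
    d <- deg[, x]
    connected <- d > 0
    # intra-layer block: column-normalised adjacency scaled by (1 - delta)
    if (any(connected)) {
      Asub <- A[, connected, drop = FALSE]
      trip <- Matrix::summary(Asub)
      cols <- which(connected)[trip$j]
      ti <- c(ti, off + trip$i)
      tj <- c(tj, off + cols)
      tx <- c(tx, (1 - delta) * trip$x / d[cols])
    }
    if (L > 1 && delta > 0) {
      # inter-layer jumps: same node, other layers
      jump <- ifelse(connected, delta / (L - 1), 1 / (L - 1))
      for (y in seq_len(L)[-x]) {
        offy <- (y - 1L) * n
        nz <- which(jump > 0 & !isolated_everywhere)
        ti <- c(ti, offy + nz)
        tj <- c(tj, off + nz)
        tx <- c(tx, jump[nz])
      }
    }
    # self-loops keep columns stochastic where the walker has nowhere to go:
    # nodes isolated in every layer, and (with delta = 0, where the operator
    # must stay block-diagonal) nodes isolated in this layer
    selfers <- if (L == 1 || delta == 0) {
      which(!connected)
    } else {
      which(isolated_everywhere)
    }
    if (length(selfers) > 0) {
      ti <- c(ti, off + selfers)
      tj <- c(tj, off + selfers)
      tx <- c(tx, rep(1, length(selfers)))
    }
  }
  nm <- supra_names(mx)
  M <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(L * n, L * n),
                            dimnames = list(nm, nm))
  structure(
    list(matrix = M, delta = delta, L = L, n = n,
         node_index = mx$node_index),
    class = "supra_transition"
  )
}

#' @export
print.supra_transition <- function(x, ...) {
  cat("<supra_transition> ", x$L, " x ", x$n, " = ", x$L * x$n,
      " supra nodes, delta = ", x$delta, "\n", sep = "")
  invisible(x)
}

#' Write / read a multiplex network as TSV layers plus a JSON manifest
#'
#' The on-disk form is a directory of per-layer 3-column TSV edge lists and a
#' `manifest.json` naming the layers in order with the node policy, so runs
#' are reproducible from plain text.
#'
#' @param mx a `multiplex_network`.
#' @param dir directory to write into (created if absent).
#' @return `write_multiplex`: the manifest path, invisibly.
#'   `read_multiplex`: a `multiplex_network`.
#' @export
write_multiplex <- function(mx, dir) {
  stopifnot(inherits(mx, "multiplex_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(mx$L)
  for (i in seq_len(mx$L)) {
    g <- mx$layers[[i]]
    files[i] <- paste0(g$name, ".tsv")
    utils::write.table(g$edges, file.path(dir, files[i]),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  manifest <- list(
    layers = lapply(seq_len(mx$L), function(i) {
      list(name = mx$layers[[i]]$name, file = files[i])
    }),
    node_policy = mx$node_policy,
    nodes = mx$node_index
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @param manifest path to a `manifest.json` written by [write_multiplex()]
#'   (or the directory containing it).
#' @rdname write_multiplex
#' @export
read_multiplex <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.json")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  spec <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  nodes <- as.character(unlist(spec$nodes))
  layers <- lapply(spec$layers, function(ly) {
    g <- read_edge_list(file.path(dir, ly$file), weighted = TRUE,
                        name = ly$name)
    layer_graph(g$edges, nodes = nodes, name = ly$name)
  })
  build_multiplex(layers, node_policy = spec$node_policy %||% "intersection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a seed-gene list (one identifier per line)
#' @param path path to the list; `#` comments and blanks ignored.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  raw <- readLines(path)
  genes <- trimws(raw[!grepl("^\\s*(#|$)", raw)])
  if (length(genes) == 0) stop("no genes in ", path)
  unique(genes)
}
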