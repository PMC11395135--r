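#' Construct a network layer
#'
#' A `layer_graph` is one undirected layer of a multiplex biological network:
#' genes (or proteins) as nodes, weighted undirected edges, no self-loops and
#' no duplicate edges. It is the unit that [build_multiplex()] fuses.
#'
#' Edges are canonicalised on construction: self-loops are dropped, each
#' unordered pair is stored once with `from < to` lexicographically, and
#' duplicate pairs are collapsed keeping the maximum weight (evidence-union
#' semantics for multi-source merging).
#'
#' @param edges data frame with columns `from`, `to` and optionally `weight`
#'   (default 1). Character node identifiers.
#' @param nodes optional character vector of node identifiers; the node set is
#'   the union of `nodes` and all edge endpoints, so isolated nodes can be kept.
#' @param name label for the layer.
#' @return An object of class `layer_graph`: a list with elements `name`,
#'   `nodes` (sorted character vector) and `edges` (data frame `from`, `to`,
#'   `weight`, sorted, `from < to`).
#' @examples
#' g <- layer_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
#' n_nodes(g)
#' @export
layer_graph <- function(edges = NULL, nodes = NULL, name = "layer") {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    stop("edges must have columns 'from' and 'to'")
  }
  if (!"weight" %in% names(edges)) edges$weight <- rep(1, nrow(edges))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(is.na(edges$weight)) || any(edges$weight < 0)) {
    stop("edge weights must be non-negative numbers")
  }

  n_self <- sum(edges$from == edges$to)
  if (n_self > 0) {
    message("layer_graph('", name, "'): dropped ", n_self, " self-loop(s)")
    edges <- edges[edges$from != edges$to, , drop = FALSE]
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges <- data.frame(from = a, to = b, weight = edges$weight,
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    key <- paste(edges$from, edges$to, sep = "\r")
    w <- tapply(edges$weight, key, max)
    uq <- !duplicated(key)
    edges <- edges[uq, , drop = FALSE]
    edges$weight <- as.numeric(w[paste(edges$from, edges$to, sep = "\r")])
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }

  all_nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(
    list(name = name, nodes = all_nodes, edges = edges),
    class = "layer_graph"
  )
}

#' @export
print.layer_graph <- function(x, ...) {
  cat("<layer_graph> '", x$name, "': ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Number of nodes / edges of a layer
#' @param g a `layer_graph`.
#' @return integer count.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' Validate layer_graph invariants
#'
#' Checks the structural invariants every layer must satisfy: no self-loops,
#' no duplicate unordered pairs, every endpoint in the node set, non-negative
#' weights. Used by the test suite on every constructed graph.
#'
#' @param g object to validate.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_layer_graph <- function(g) {
  stopifnot(inherits(g, "layer_graph"))
  e <- g$edges
  if (any(e$from == e$to)) stop("self-loop present")
  if (anyDuplicated(paste(e$from, e$to))) stop("duplicate edge present")
  if (any(e$from > e$to)) stop("edge pair not in canonical order")
  if (!all(c(e$from, e$to) %in% g$nodes)) stop("edge endpoint not in node set")
  if (any(e$weight < 0)) stop("negative edge weight")
  if (anyDuplicated(g$nodes)) stop("duplicate node identifier")
  invisible(TRUE)
}

#' Read a network layer from a TSV edge list
#'
#' Parses a two- or three-column edge list (`node_a`, `node_b`\[, `weight`\]).
#' Lines starting with `#` and blank lines are ignored. Self-loops are dropped
#' (with a message giving the count) and duplicate pairs collapsed keeping the
#' maximum weight.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator, default tab (any run of whitespace also
#'   accepted).
#' @param weighted if `TRUE`, a numeric third column is required and used as
#'   the edge weight; otherwise all weights are 1.
#' @param name layer label; defaults to the file name without extension.
#' @return A [layer_graph()].
#' @export
read_edge_list <- function(path, delimiter = "\t", weighted = FALSE,
                           name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (length(lines) == 0) stop("empty edge list: ", path)

  split_re <- if (identical(delimiter, "\t")) "[\t ]+" else delimiter
  parts <- strsplit(trimws(lines), split_re)
  nf <- lengths(parts)
  bad <- which(nf < 2 | (weighted & nf < 3))
  if (length(bad) > 0) {
    stop("malformed edge list line ", lineno[bad[1]], " in ", path,
         ": expected at least ", if (weighted) 3 else 2, " fields")
  }
  from <- vapply(parts, `[[`, character(1), 1)
  to <- vapply(parts, `[[`, character(1), 2)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
    if (any(is.na(w))) {
      stop("non-numeric weight at line ", lineno[which(is.na(w))[1]],
           " in ", path)
    }
  } else {
    w <- rep(1, length(from))
  }
  layer_graph(data.frame(from = from, to = to, weight = w,
                         stringsAsFactors = FALSE), name = name)
}

#' Read a protein-to-gene identifier mapping table
#'
#' Two-column TSV (`protein_id`, `gene_id`); many proteins may map to one gene
#' but each protein maps to exactly one gene.
#'
#' @param path path to the mapping TSV.
#' @param header if `TRUE`, the first non-comment line is a header and skipped.
#' @return Named character vector: names are source (protein) identifiers,
#'   values target (gene) identifiers.
#' @export
read_id_mapping <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("mapping table needs two columns: ", path)
  m <- stats::setNames(df[[2]], df[[1]])
  if (anyDuplicated(names(m))) {
    dup <- names(m)[duplicated(names(m))][1]
    stop("identifier '", dup, "' maps to more than one target in ", path)
  }
  m
}

#' Map node identifiers of a layer
#'
#' Renames every node through a many-to-one identifier mapping (for example
#' protein to gene). Nodes absent from the mapping are removed together with
#' their incident edges; edges whose endpoints collapse onto one gene become
#' self-loops and are dropped; duplicate edges arising from the collapse keep
#' the maximum weight.
#'
#' @param g a [layer_graph()].
#' @param mapping named character vector (old identifier -> new identifier),
#'   e.g. from [read_id_mapping()].
#' @return A mapped [layer_graph()].
#' @export
map_identifiers <- function(g, mapping) {
  stopifnot(inherits(g, "layer_graph"))
  if (anyDuplicated(names(mapping))) stop("mapping keys must be unique")
  known <- g$nodes %in% names(mapping)
  if (any(!known)) {
    message("map_identifiers('", g$name, "'): removed ", sum(!known),
            " node(s) without a mapping entry")
  }
  kept <- g$nodes[known]
  e <- g$edges
  e <- e[e$from %in% kept & e$to %in% kept, , drop = FALSE]
  e$from <- unname(mapping[e$from])
  e$to <- unname(mapping[e$to])
  layer_graph(e, nodes = unname(mapping[kept]), name = g$name)
}

#' Merge several layers into one
#'
#' Node set is the union of node sets, edge set the union of edge sets;
#' an edge present in several inputs keeps its maximum weight. Used to fuse
#' interaction evidence from multiple sources into a single layer.
#'
#' @param graphs list of [layer_graph()] objects (at least one).
#' @param name label for the merged layer.
#' @return A merged [layer_graph()].
#' @export
merge_layers <- function(graphs, name = "merged") {
  if (length(graphs) < 1) stop("merge_layers needs at least one graph")
  lapply(graphs, function(g) stopifnot(inherits(g, "layer_graph")))
  edges <- do.call(rbind, lapply(graphs, function(g) g$edges))
  nodes <- unique(unlist(lapply(graphs, function(g) g$nodes)))
  layer_graph(edges, nodes = nodes, name = name)
}

#' Build a co-expression layer from an expression matrix
#'
#' Computes all pairwise Pearson correlations between gene expression profiles
#' and keeps gene pairs passing a correlation threshold as edges, weighted by
#' the absolute correlation. Genes with zero variance are excluded
#' (correlation undefined); genes with no passing edge are omitted from the
#' layer.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns; at least 3 samples.
#' @param threshold correlation cutoff in \[0, 1\]. The cutoff is a modelling
#'   choice, not a universal constant; 0.8 is a common stringent default.
#' @param use_absolute if `TRUE` the criterion is `|r| >= threshold`
#'   (anti-correlated pairs also connect), otherwise `r >= threshold`.
#' @param name layer label.
#' @return A [layer_graph()] whose edge weights are `|r|`.
#' @export
build_coexpression <- function(expr, threshold = 0.8, use_absolute = FALSE,
                               name = "coexpression") {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) stop("expression matrix must be numeric")
  if (ncol(expr) < 3) stop("need at least 3 samples to correlate")
  if (is.null(rownames(expr))) stop("expression matrix needs gene rownames")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")

  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    message("build_coexpression: excluded ", sum(v == 0),
            " zero-variance gene(s)")
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2) return(layer_graph(name = name))

  r <- stats::cor(t(expr))
  crit <- if (use_absolute) abs(r) >= threshold else r >= threshold
  crit[lower.tri(crit, diag = TRUE)] <- FALSE
  idx <- which(crit, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(r)[idx[, 1]],
    to = rownames(r)[idx[, 2]],
    weight = abs(r[idx]),
    stringsAsFactors = FALSE
  )
  layer_graph(edges, name = name)
}

#' Read an expression matrix TSV
#'
#' First column gene identifier, remaining columns numeric sample values,
#' header row of sample names.
#'
#' @param path path to the TSV.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression value in ", path)
  rownames(m) <- genes
  m
}
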