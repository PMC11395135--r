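#' Eigenvector centrality of a layer by power iteration
#'
#' Node importance proportional to the summed importance of neighbours:
#' the dominant eigenvector of the (weighted) adjacency matrix,
#' `c_i = (1 / lambda) * sum_j A_ij c_j`. Computed by power iteration from a
#' uniform positive start, renormalised each step, until the L1 change between
#' successive (sum-normalised) iterates drops below `tol` or `max_iter` is
#' reached. The returned values are max-normalised (largest value 1); isolated
#' nodes get 0. Edge weights, if present, enter as `A_ij = weight`.
#'
#' On a disconnected layer the power iteration concentrates on the component
#' with the largest dominant eigenvalue; nodes of other components decay
#' towards 0. That is intended: downstream, zero-centrality nodes receive the
#' minimum restart probability.
#'
#' @param g a [layer_graph()], nonempty.
#' @param tol L1 convergence tolerance, default `1e-12`.
#' @param max_iter iteration cap, default 10000; non-convergence warns and
#'   returns the current iterate.
#' @return An object of class `centrality_vector`: list with `values` (named
#'   non-negative numeric, max = 1 unless the layer has no edges) and
#'   `lambda_max` (dominant eigenvalue estimate).
#' @examples
#' star <- layer_graph(data.frame(from = "hub", to = c("a", "b", "c")))
#' eigenvector_centrality(star)$values  # hub 1, leaves 1/sqrt(3)
#' @export
eigenvector_centrality <- function(g, tol = 1e-12, max_iter = 10000) {
  stopifnot(inherits(g, "layer_graph"))
  n <- length(g$nodes)
  if (n == 0) stop("empty graph: eigenvector centrality undefined")
  if (nrow(g$edges) == 0) {
    return(structure(
      list(values = stats::setNames(rep(0, n), g$nodes), lambda_max = 0),
      class = "centrality_vector"
    ))
  }
  A <- layer_adjacency(g)
  x <- rep(1 / n, n)
  lambda <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # shifted iteration (A + I): same eigenvectors, but the top eigenvalue is
    # strictly dominant, so bipartite layers (eigenvalues +/- lambda) cannot
    # make the iteration oscillate
    y <- as.numeric(A %*% x) + x
    s <- sum(y)
    if (s == 0) break  # cannot happen with a positive start on a symmetric A
    ynorm <- y / s
    if (sum(abs(ynorm - x)) < tol) {
      x <- ynorm
      converged <- TRUE
      break
    }
    x <- ynorm
  }
  if (!converged) {
    warning("eigenvector centrality did not converge in ", max_iter,
            " iterations (layer '", g$name, "'); returning current iterate")
  }
  x[Matrix::colSums(A) == 0] <- 0  # isolated nodes: empty neighbour sum
  # Rayleigh quotient on the converged direction
  Ax <- as.numeric(A %*% x)
  lambda <- sum(x * Ax) / sum(x * x)
  vals <- x / max(x)
  structure(
    list(values = stats::setNames(vals, g$nodes), lambda_max = lambda),
    class = "centrality_vector"
  )
}

#' @export
print.centrality_vector <- function(x, ...) {
  cat("<centrality_vector> n =", length(x$values),
      " lambda_max =", format(x$lambda_max), "\n")
  invisible(x)
}

new_restart_profile <- function(restart, mode, r_min = NA_real_,
                                r_max = NA_real_) {
  structure(
    list(restart = restart, move = 1 - restart, mode = mode,
         r_min = r_min, r_max = r_max),
    class = "restart_profile"
  )
}

#' Node-specific restart probabilities for the multiplex walker
#'
#' Builds the supra restart vector (length `L * n`) and its complement, the
#' movement vector. In `"uniform"` mode every entry equals `r_uniform` and the
#' walker reduces to classical RWR. In `"centrality"` mode each layer's
#' eigenvector centrality is affine-rescaled from its own \[min, max\] onto
#' \[`r_min`, `r_max`\], so more central (hub) genes restart the walker more
#' often while every entry stays strictly inside (0, 1) — no node is absorbing
#' or restart-free. A layer whose centralities are all equal (e.g. a cycle)
#' maps to the midpoint `(r_min + r_max) / 2`.
#'
#' @param mx a `multiplex_network`.
#' @param mode `"centrality"` (default) or `"uniform"`.
#' @param r_uniform restart probability used in uniform mode, in (0, 1);
#'   default 0.7, the field-standard RWR value.
#' @param r_min,r_max clamp bounds for the centrality rescaling,
#'   `0 < r_min < r_max < 1`; defaults 0.05 and 0.95.
#' @param tol,max_iter passed to [eigenvector_centrality()].
#' @return An object of class `restart_profile`: list with `restart` and
#'   `move` (named supra vectors, `move = 1 - restart` exactly), `mode`,
#'   `r_min`, `r_max`.
#' @export
restart_profile <- function(mx, mode = c("centrality", "uniform"),
                            r_uniform = 0.7, r_min = 0.05, r_max = 0.95,
                            tol = 1e-12, max_iter = 10000) {
  stopifnot(inherits(mx, "multiplex_network"))
  mode <- match.arg(mode)
  nm <- supra_names(mx)
  if (mode == "uniform") {
    if (r_uniform <= 0 || r_uniform >= 1) stop("r_uniform must be in (0, 1)")
    return(new_restart_profile(
      stats::setNames(rep(r_uniform, mx$L * mx$n), nm), mode
    ))
  }
  if (!(r_min > 0 && r_min < r_max && r_max < 1)) {
    stop("need 0 < r_min < r_max < 1")
  }
  per_layer <- lapply(mx$layers, function(g) {
    ec <- eigenvector_centrality(g, tol = tol, max_iter = max_iter)$values
    lo <- min(ec)
    hi <- max(ec)
    if (hi == lo) {
      rep((r_min + r_max) / 2, length(ec))
    } else {
      r_min + (ec - lo) / (hi - lo) * (r_max - r_min)
    }
  })
  new_restart_profile(stats::setNames(unlist(per_layer), nm), mode,
                      r_min, r_max)
}

#' @export
print.restart_profile <- function(x, ...) {
  cat("<restart_profile> mode =", x$mode, " length =", length(x$restart),
      " range = [", format(min(x$restart)), ",", format(max(x$restart)), "]\n")
  invisible(x)
}

#' Export a restart profile for inspection
#'
#' @param profile a `restart_profile`.
#' @param mx the `multiplex_network` it was built on.
#' @param path TSV output path (columns: layer, node, restart_probability).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, mx, path) {
  df <- data.frame(
    layer = rep(vapply(mx$layers, function(g) g$name, character(1)),
                each = mx$n),
    node = rep(mx$node_index, mx$L),
    restart_probability = unname(profile$restart),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
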