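#' Initial supra probability distribution over seed genes
#'
#' Seed genes receive the walker's restart mass. Layer `x` gets total mass
#' `tau[x]` (the layer-importance weights, non-negative and summing to 1;
#' default uniform `1/L`, all layers equally important), split uniformly over
#' the seed genes within the layer; all other entries are 0.
#'
#' @param mx a `multiplex_network`.
#' @param seeds character vector of seed gene identifiers, all present in
#'   `mx$node_index`, nonempty.
#' @param tau numeric vector of length `L`, entries >= 0 summing to 1;
#'   default `rep(1/L, L)`.
#' @return Named numeric supra vector of length `L * n` summing to 1.
#' @export
initial_distribution <- function(mx, seeds, tau = NULL) {
  stopifnot(inherits(mx, "multiplex_network"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) stop("seed set is empty")
  missing <- setdiff(seeds, mx$node_index)
  if (length(missing) > 0) {
    stop("seed gene(s) not in the multiplex node set: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  if (is.null(tau)) tau <- rep(1 / mx$L, mx$L)
  if (length(tau) != mx$L || any(tau < 0) || abs(sum(tau) - 1) > 1e-8) {
    stop("tau must have length L, entries >= 0, and sum to 1")
  }
  p0 <- numeric(mx$L * mx$n)
  pos <- match(seeds, mx$node_index)
  for (x in seq_len(mx$L)) {
    p0[(x - 1) * mx$n + pos] <- tau[x] / length(seeds)
  }
  stats::setNames(p0, supra_names(mx))
}

#' Random walk with multi-restart probabilities (and uniform-restart RWR)
#'
#' Iterates the propagation update
#' \deqn{p_{t+1} = diag(1 - R) \, N p_t + z \, p_0}
#' where `N` is the column-stochastic supra-transition operator, `R` the
#' node-specific restart vector, `p_0` the seed distribution, and `z` the
#' scalar restart mass. With a uniform profile (`R = r` everywhere) this is
#' exactly classical RWR, `p <- (1 - r) N p + r p0`.
#'
#' Two definitions of `z` are supported. The default, `z_mode =
#' "conserving"`, takes `z = R . (N p_t)` — the restart mass of walkers
#' *after* the move — which conserves total probability exactly at every
#' iterate. `z_mode = "paper_literal"` updates `z` from the pre-step
#' distribution (`z = R . p_t`) as sometimes written; that recipe does not
#' conserve mass on its own, so each iterate is renormalised to sum 1.
#'
#' The iteration stops after exactly `max_iter` steps (`stop_rule =
#' "fixed_iter"`, default 20 steps) or when the L1 change between iterates
#' falls below `tol` (`stop_rule = "tolerance"`, capped at `max_iter`).
#' The final supra vector is collapsed to per-gene scores by summing each
#' gene's entries across layers.
#'
#' @param mx a `multiplex_network`.
#' @param N a `supra_transition` built on `mx`.
#' @param profile a `restart_profile` of matching length.
#' @param seeds character vector of seed genes.
#' @param tau layer weights, see [initial_distribution()].
#' @param max_iter iteration count (fixed_iter) or cap (tolerance).
#' @param tol L1 tolerance for `stop_rule = "tolerance"`.
#' @param stop_rule `"fixed_iter"` or `"tolerance"`.
#' @param z_mode `"conserving"` or `"paper_literal"`.
#' @return An object of class `score_vector`: list with `scores` (named
#'   per-gene numeric summing to 1), `supra` (final supra distribution), and
#'   `provenance` (run parameters, iterations used, final L1 change).
#' @export
rwmrp <- function(mx, N, profile, seeds, tau = NULL,
                  max_iter = 20, tol = 1e-10,
                  stop_rule = c("fixed_iter", "tolerance"),
                  z_mode = c("conserving", "paper_literal")) {
  stopifnot(inherits(mx, "multiplex_network"),
            inherits(N, "supra_transition"),
            inherits(profile, "restart_profile"))
  stop_rule <- match.arg(stop_rule)
  z_mode <- match.arg(z_mode)
  Ln <- mx$L * mx$n
  if (nrow(N$matrix) != Ln || length(profile$restart) != Ln) {
    stop("dimension mismatch between multiplex, transition and profile")
  }
  p0 <- initial_distribution(mx, seeds, tau)
  R <- unname(profile$restart)
  mv <- unname(profile$move)
  M <- N$matrix

  p <- unname(p0)
  delta_l1 <- NA_real_
  iters <- 0L
  if (z_mode == "paper_literal") z <- sum(R * p)
  for (t in seq_len(max_iter)) {
    q <- as.numeric(M %*% p)
    if (z_mode == "conserving") {
      z <- sum(R * q)
      p_new <- mv * q + z * unname(p0)
    } else {
      p_new <- mv * q + z * unname(p0)
      p_new <- p_new / sum(p_new)
      z <- sum(R * p)
    }
    delta_l1 <- sum(abs(p_new - p))
    p <- p_new
    iters <- t
    if (stop_rule == "tolerance" && delta_l1 < tol) break
  }

  scores <- numeric(mx$n)
  for (x in seq_len(mx$L)) {
    scores <- scores + p[(x - 1) * mx$n + seq_len(mx$n)]
  }
  structure(
    list(
      scores = stats::setNames(scores, mx$node_index),
      supra = stats::setNames(p, supra_names(mx)),
      provenance = list(
        mode = profile$mode, delta = N$delta,
        tau = if (is.null(tau)) rep(1 / mx$L, mx$L) else tau,
        seeds = sort(unique(as.character(seeds))),
        z_mode = z_mode, stop_rule = stop_rule,
        iterations = iters, final_l1_change = delta_l1
      )
    ),
    class = "score_vector"
  )
}

#' @export
print.score_vector <- function(x, ...) {
  top <- utils::head(sort(x$scores, decreasing = TRUE), 5)
  cat("<score_vector> n =", length(x$scores), "genes;",
      x$provenance$iterations, "iterations\n  top:",
      paste(names(top), format(top, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Rank genes by propagation score
#'
#' Sorts genes by descending score. Seed genes are excluded by default (they
#' trivially score high). Tied scores all receive the worst (maximum) rank of
#' their tied block, so a tie never flatters a gene's rank — this keeps
#' leave-one-out evaluation conservative. Row order is deterministic:
#' descending score, then gene identifier.
#'
#' @param s a `score_vector` from [rwmrp()], or a named numeric vector.
#' @param seeds seed genes to exclude (default none).
#' @param exclude_seeds drop the seeds from the ranking (default `TRUE`).
#' @return data frame with columns `gene`, `score`, `rank`.
#' @export
rank_genes <- function(s, seeds = character(), exclude_seeds = TRUE) {
  scores <- if (inherits(s, "score_vector")) s$scores else s
  stopifnot(!is.null(names(scores)))
  if (exclude_seeds && length(seeds) > 0) {
    scores <- scores[!(names(scores) %in% seeds)]
  }
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  data.frame(
    gene = names(scores),
    score = unname(scores),
    rank = rank(-scores, ties.method = "max"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
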