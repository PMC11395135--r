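#' Leave-one-out cross-validation of the multiplex walker
#'
#' Each gene of the test set (the known genes present in the multiplex) is
#' withheld in turn; the walker runs with the remaining known genes as seeds,
#' all non-seed genes are ranked, and the withheld gene's rank is recorded.
#' Small ranks mean the network plus walker recover the withheld gene from
#' its peers. The restart profile and supra-transition operator depend only
#' on the network, not on the seeds, so they are computed once and reused
#' across folds.
#'
#' The left-out gene's rank is computed among non-seed genes (it is, by
#' construction, not a seed in its own fold).
#'
#' @param mx a `multiplex_network`.
#' @param known_genes character vector of known (e.g. stress-responsive)
#'   genes; the test set is their intersection with `mx$node_index` and must
#'   have at least 2 members.
#' @param mode,r_uniform,r_min,r_max profile settings, see [restart_profile()].
#' @param delta inter-layer jump probability, see [build_supra_transition()].
#' @param tau,max_iter,tol,stop_rule,z_mode walker settings, see [rwmrp()].
#' @param track_genes optional character vector of extra (non-seed) genes
#'   whose per-fold ranks are recorded alongside the left-out gene's — useful
#'   for comparing known genes against matched random genes scored in the
#'   same folds.
#' @return An object of class `loocv_result`: list with `ranks` (named
#'   integer, one per test gene), `test_set` and `test_set_size`, `n_ranked`
#'   (genes ranked per fold), `curve` (data frame `k`, `fraction`),
#'   `tracked_ranks` (matrix fold x tracked gene, if requested) and `config`.
#' @export
loocv <- function(mx, known_genes,
                  mode = c("centrality", "uniform"),
                  r_uniform = 0.7, r_min = 0.05, r_max = 0.95,
                  delta = 0.5, tau = NULL,
                  max_iter = 20, tol = 1e-10,
                  stop_rule = c("fixed_iter", "tolerance"),
                  z_mode = c("conserving", "paper_literal"),
                  track_genes = NULL) {
  stopifnot(inherits(mx, "multiplex_network"))
  mode <- match.arg(mode)
  stop_rule <- match.arg(stop_rule)
  z_mode <- match.arg(z_mode)

  test_set <- sort(intersect(unique(as.character(known_genes)),
                             mx$node_index))
  if (length(test_set) < 2) {
    stop("test set (known genes present in the network) must have >= 2 ",
         "members; got ", length(test_set))
  }
  N <- build_supra_transition(mx, delta = delta)
  profile <- restart_profile(mx, mode = mode, r_uniform = r_uniform,
                             r_min = r_min, r_max = r_max)
  track_genes <- setdiff(unique(as.character(track_genes)), test_set)

  ranks <- stats::setNames(integer(length(test_set)), test_set)
  tracked <- if (length(track_genes) > 0) {
    matrix(NA_integer_, nrow = length(test_set), ncol = length(track_genes),
           dimnames = list(test_set, track_genes))
  } else NULL
  n_ranked <- NA_integer_
  for (i in seq_along(test_set)) {
    left_out <- test_set[i]
    seeds <- test_set[-i]
    sv <- rwmrp(mx, N, profile, seeds, tau = tau, max_iter = max_iter,
                tol = tol, stop_rule = stop_rule, z_mode = z_mode)
    rk <- rank_genes(sv, seeds = seeds, exclude_seeds = TRUE)
    ranks[left_out] <- rk$rank[match(left_out, rk$gene)]
    n_ranked <- nrow(rk)
    if (!is.null(tracked)) {
      tracked[i, ] <- rk$rank[match(track_genes, rk$gene)]
    }
  }

  res <- structure(
    list(
      ranks = ranks,
      test_set = test_set,
      test_set_size = length(test_set),
      n_ranked = n_ranked,
      tracked_ranks = tracked,
      config = list(mode = mode, r_uniform = r_uniform, r_min = r_min,
                    r_max = r_max, delta = delta, tau = tau,
                    max_iter = max_iter, tol = tol, stop_rule = stop_rule,
                    z_mode = z_mode)
    ),
    class = "loocv_result"
  )
  res$curve <- rank_curve(res)
  res
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("<loocv_result>", x$test_set_size, "folds;",
      "median left-out rank =", stats::median(x$ranks),
      "; top-300 fraction =", format(curve_at(x, 300), digits = 3), "\n")
  invisible(x)
}

#' Fraction of left-out genes ranked within the top k
#'
#' The headline cross-validation metric: of the withheld known genes, what
#' fraction was recovered at rank `<= k`.
#'
#' @param res a `loocv_result`.
#' @param k rank threshold, `>= 1`.
#' @return Fraction in \[0, 1\].
#' @export
curve_at <- function(res, k) {
  stopifnot(inherits(res, "loocv_result"), k >= 1)
  sum(res$ranks <= k) / res$test_set_size
}

#' Cumulative rank-distribution curve
#'
#' Fraction of left-out genes with rank `<= k` over a grid of thresholds.
#' The default grid covers 1..max rank, subsampled roughly logarithmically,
#' and always includes k = 300 (the conventional top-300 cutoff) when the
#' ranking is that long.
#'
#' @param res a `loocv_result`.
#' @param k_grid integer thresholds; default as described.
#' @return data frame with columns `k` and `fraction` (nondecreasing in `k`).
#' @export
rank_curve <- function(res, k_grid = NULL) {
  stopifnot(inherits(res, "loocv_result"))
  if (is.null(k_grid)) {
    kmax <- max(res$n_ranked, max(res$ranks))
    k_grid <- unique(c(
      round(exp(seq(0, log(kmax), length.out = 50))),
      if (kmax >= 300) 300L, kmax
    ))
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  data.frame(
    k = k_grid,
    fraction = vapply(k_grid, function(k) curve_at(res, k), numeric(1))
  )
}

#' Compare walker configurations by LOOCV on identical folds
#'
#' Runs [loocv()] once per configuration on the same multiplex and known-gene
#' set (folds are identical by construction: one per test gene, in sorted
#' order) and returns a long table of cumulative rank curves ready for
#' plotting.
#'
#' @param mx a `multiplex_network`.
#' @param known_genes known gene set, see [loocv()].
#' @param configs named list of configuration lists; each element holds
#'   arguments for [loocv()] (e.g. `list(mode = "uniform", r_uniform = 0.7)`).
#'   At least 2 configurations.
#' @param k_grid shared rank-threshold grid; default: union of each result's
#'   default grid.
#' @return data frame with columns `config`, `k`, `fraction`; attribute
#'   `"results"` holds the full `loocv_result` objects.
#' @export
compare_methods <- function(mx, known_genes, configs, k_grid = NULL) {
  if (length(configs) < 2) stop("need at least 2 configurations to compare")
  if (is.null(names(configs)) || any(names(configs) == "")) {
    names(configs) <- paste0("config", seq_along(configs))
  }
  results <- lapply(configs, function(cfg) {
    do.call(loocv, c(list(mx = mx, known_genes = known_genes), cfg))
  })
  if (is.null(k_grid)) {
    k_grid <- sort(unique(unlist(lapply(results, function(r) r$curve$k))))
  }
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    cv <- rank_curve(results[[nm]], k_grid = k_grid)
    data.frame(config = nm, k = cv$k, fraction = cv$fraction,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  attr(tab, "results") <- results
  tab
}

#' Plot cumulative rank curves
#'
#' Renders the output of [compare_methods()] as cumulative-recovery curves
#' (fraction of left-out genes within the top k, against k).
#'
#' @param curves data frame with columns `config`, `k`, `fraction`.
#' @param log_x log-scale the rank axis (default `TRUE`).
#' @return A ggplot object if ggplot2 is installed, otherwise draws with base
#'   graphics and returns `NULL` invisibly.
#' @export
plot_rank_curves <- function(curves, log_x = TRUE) {
  stopifnot(all(c("config", "k", "fraction") %in% names(curves)))
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(
      curves,
      ggplot2::aes(x = .data$k, y = .data$fraction, colour = .data$config)
    ) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "rank threshold k",
                    y = "fraction of left-out genes ranked <= k",
                    colour = NULL) +
      ggplot2::theme_minimal()
    if (log_x) p <- p + ggplot2::scale_x_log10()
    return(p)
  }
  cfgs <- unique(curves$config)
  graphics::plot(NULL, xlim = range(curves$k), ylim = c(0, 1),
                 log = if (log_x) "x" else "",
                 xlab = "rank threshold k", ylab = "fraction <= k")
  for (i in seq_along(cfgs)) {
    sub <- curves[curves$config == cfgs[i], ]
    graphics::lines(sub$k, sub$fraction, type = "s", col = i)
  }
  graphics::legend("bottomright", legend = cfgs, col = seq_along(cfgs),
                   lty = 1, bty = "n")
  invisible(NULL)
}
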