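#' Validated run configuration
#'
#' Collects every tunable of the pipeline with its default, validating each
#' against its domain before any computation. Defaults follow the method's
#' conventional values: 20 propagation iterations, top-300 potential genes,
#' candidate filter at >= 3 partners with score >= 0.9, uniform layer weights.
#'
#' @param node_policy `"intersection"` or `"union"` (layer fusion).
#' @param delta inter-layer jump probability in \[0, 1\].
#' @param tau layer weights (`NULL` = uniform `1/L`).
#' @param mode restart profile: `"centrality"` or `"uniform"`.
#' @param r_uniform uniform restart probability in (0, 1).
#' @param r_min,r_max centrality-rescaling bounds, `0 < r_min < r_max < 1`.
#' @param stop_rule `"fixed_iter"` or `"tolerance"`.
#' @param max_iter iteration count / cap, `>= 1`.
#' @param tol convergence tolerance, `> 0`.
#' @param z_mode `"conserving"` or `"paper_literal"`, see [rwmrp()].
#' @param top_k potential genes kept from the ranking, `>= 1`.
#' @param min_partners,min_score candidate-filter thresholds, see
#'   [select_candidates()].
#' @param generator_seed RNG seed used by `simulate` stages.
#' @return An object of class `run_config` (validated list).
#' @export
run_config <- function(node_policy = "intersection", delta = 0.5, tau = NULL,
                       mode = "centrality", r_uniform = 0.7,
                       r_min = 0.05, r_max = 0.95,
                       stop_rule = "fixed_iter", max_iter = 20, tol = 1e-10,
                       z_mode = "conserving", top_k = 300,
                       min_partners = 3, min_score = 0.9,
                       generator_seed = 1) {
  node_policy <- match.arg(node_policy, c("intersection", "union"))
  mode <- match.arg(mode, c("centrality", "uniform"))
  stop_rule <- match.arg(stop_rule, c("fixed_iter", "tolerance"))
  z_mode <- match.arg(z_mode, c("conserving", "paper_literal"))
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  if (r_uniform <= 0 || r_uniform >= 1) stop("r_uniform must be in (0, 1)")
  if (!(r_min > 0 && r_min < r_max && r_max < 1)) {
    stop("need 0 < r_min < r_max < 1")
  }
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  if (top_k < 1) stop("top_k must be >= 1")
  if (min_partners < 1) stop("min_partners must be >= 1")
  if (min_score < 0 || min_score > 1) stop("min_score must be in [0, 1]")
  if (!is.null(tau) && (any(tau < 0) || abs(sum(tau) - 1) > 1e-8)) {
    stop("tau entries must be >= 0 and sum to 1")
  }
  structure(
    list(node_policy = node_policy, delta = delta, tau = tau, mode = mode,
         r_uniform = r_uniform, r_min = r_min, r_max = r_max,
         stop_rule = stop_rule, max_iter = as.integer(max_iter), tol = tol,
         z_mode = z_mode, top_k = as.integer(top_k),
         min_partners = as.integer(min_partners), min_score = min_score,
         generator_seed = as.integer(generator_seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat("  ", nm, " = ", paste(format(x[[nm]]), collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; listed keys override [run_config()] defaults.
#'
#' @param path path to a YAML (`.yml`/`.yaml`, requires the yaml package) or
#'   JSON file of configuration fields.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

provenance_header <- function(config, input_paths) {
  sums <- vapply(input_paths, function(p) {
    unname(tools::md5sum(p))
  }, character(1))
  list(
    package = "rwmrp",
    version = as.character(utils::packageVersion("rwmrp")),
    config = config[!vapply(config, is.null, logical(1))],
    inputs = as.list(stats::setNames(sums, basename(input_paths)))
  )
}

write_tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full prioritization pipeline
#'
#' Executes the configured stages in order: read the multiplex and seed
#' genes, build the supra-transition operator and restart profile, propagate,
#' rank non-seed genes, cross-validate, and (when a score table is supplied)
#' filter the top-ranked potential genes into candidates. All outputs are
#' plain TSV/JSON with a provenance record (configuration plus input
#' checksums) sufficient to re-run the computation; outputs carry no
#' timestamps, so identical inputs give byte-identical files.
#'
#' @param config a [run_config()].
#' @param network path to a multiplex manifest (or its directory), see
#'   [read_multiplex()].
#' @param seeds path to the known/seed gene list (one identifier per line).
#' @param score_table optional path to an interaction-score TSV for the
#'   candidate filter.
#' @param out_dir output directory (created if absent).
#' @param run_loocv run the leave-one-out evaluation (default `TRUE`).
#' @return List with `ranking`, `candidates` (or `NULL`), `loocv` (or
#'   `NULL`), and `out_dir`, invisibly; files `ranked_genes.tsv`,
#'   `candidates.tsv`, `loocv_curve.tsv`, `provenance.json` under `out_dir`.
#' @export
run_pipeline <- function(config, network, seeds, score_table = NULL,
                         out_dir = "rwmrp_out", run_loocv = TRUE) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  manifest <- if (dir.exists(network)) {
    file.path(network, "manifest.json")
  } else network
  inputs <- c(manifest, seeds, score_table)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    stop("[inputs] file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  mx <- stage("build", read_multiplex(manifest))
  seed_genes <- stage("seeds", {
    sg <- intersect(read_gene_list(seeds), mx$node_index)
    if (length(sg) == 0) stop("no seed gene is present in the network")
    sg
  })

  ranking <- stage("walk", {
    N <- build_supra_transition(mx, delta = config$delta)
    profile <- restart_profile(mx, mode = config$mode,
                               r_uniform = config$r_uniform,
                               r_min = config$r_min, r_max = config$r_max)
    sv <- rwmrp(mx, N, profile, seed_genes, tau = config$tau,
                max_iter = config$max_iter, tol = config$tol,
                stop_rule = config$stop_rule, z_mode = config$z_mode)
    rank_genes(sv, seeds = seed_genes)
  })
  potential <- ranking[ranking$rank <= config$top_k, , drop = FALSE]

  cand <- NULL
  if (!is.null(score_table)) {
    cand <- stage("candidates", {
      tab <- read_score_table(score_table)
      select_candidates(potential$gene, seed_genes, tab,
                        min_partners = config$min_partners,
                        min_score = config$min_score)
    })
  }

  cv <- NULL
  if (run_loocv && length(seed_genes) >= 2) {
    cv <- stage("loocv", {
      loocv(mx, seed_genes, mode = config$mode,
            r_uniform = config$r_uniform, r_min = config$r_min,
            r_max = config$r_max, delta = config$delta, tau = config$tau,
            max_iter = config$max_iter, tol = config$tol,
            stop_rule = config$stop_rule, z_mode = config$z_mode)
    })
  }

  stage("write", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- provenance_header(config, inputs)
    hdr <- c(
      paste0("rwmrp v", prov$version),
      paste0("mode=", config$mode, " delta=", config$delta,
             " z_mode=", config$z_mode, " stop_rule=", config$stop_rule,
             " max_iter=", config$max_iter),
      paste0("seeds=", length(seed_genes), " network=", basename(manifest))
    )
    write_tsv_with_header(ranking, file.path(out_dir, "ranked_genes.tsv"),
                          hdr)
    if (!is.null(cand)) {
      write_tsv_with_header(cand, file.path(out_dir, "candidates.tsv"), hdr)
      utils::write.table(attr(cand, "edges"),
                         file.path(out_dir, "candidate_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(cv)) {
      write_tsv_with_header(cv$curve, file.path(out_dir, "loocv_curve.tsv"),
                            hdr)
      write_tsv_with_header(
        data.frame(gene = names(cv$ranks), rank = unname(cv$ranks)),
        file.path(out_dir, "loocv_ranks.tsv"), hdr
      )
    }
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(list(ranking = ranking, candidates = cand, loocv = cv,
                 out_dir = out_dir))
}
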