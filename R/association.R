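#' Build a pairwise interaction-score table
#'
#' Holds scores in \[0, 1\] between potential genes and known genes, e.g.
#' combined scores exported from a protein-interaction database (for STRING
#' exports, map `protein1`/`protein2`/`combined_score`/1000 onto the three
#' columns). Each (potential, known) pair appears at most once.
#'
#' @param df data frame with columns `potential_gene`, `known_gene`, `score`.
#' @return An object of class `score_table` (validated data frame).
#' @export
score_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("potential_gene", "known_gene", "score") %in% names(df)))
  df$potential_gene <- as.character(df$potential_gene)
  df$known_gene <- as.character(df$known_gene)
  df$score <- as.numeric(df$score)
  if (any(is.na(df$score)) || any(df$score < 0 | df$score > 1)) {
    stop("scores must be numbers in [0, 1]")
  }
  if (anyDuplicated(paste(df$potential_gene, df$known_gene))) {
    stop("duplicate (potential_gene, known_gene) pair in score table")
  }
  class(df) <- c("score_table", "data.frame")
  df
}

#' Read an interaction-score table TSV
#'
#' Three columns: `potential_gene`, `known_gene`, `score` in \[0, 1\];
#' a header line is detected and skipped.
#'
#' @param path path to the TSV.
#' @return A [score_table()].
#' @export
read_score_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("potential_gene", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:3] <- c("potential_gene", "known_gene", "score")
  score_table(df)
}

#' Filter potential genes by strong interactions with known genes
#'
#' The association filter: a potential gene is promoted to candidate when it
#' has at least `min_partners` known genes with interaction score
#' `>= min_score`. Both thresholds are boundary-inclusive; the defaults (3
#' partners at score 0.9) implement the conventional "3 or more interactions
#' at >= 0.9" rule. Pairs absent from the table are treated as non-qualifying.
#'
#' @param potential character vector of potential genes, in ranking order
#'   (the output preserves this order), or a data frame with a `gene` column
#'   such as the output of [rank_genes()].
#' @param known character vector of known genes.
#' @param table a [score_table()].
#' @param min_partners minimum number of qualifying known partners, `>= 1`.
#' @param min_score minimum qualifying score, in \[0, 1\].
#' @return data frame with columns `candidate`, `n_partners`, and `partners`
#'   (`"known:score;..."`, scores descending), one row per candidate, in the
#'   input ranking order. Attribute `"edges"` holds the qualifying
#'   candidate-known edge list (columns `candidate`, `known_gene`, `score`)
#'   for bipartite-network visualisation.
#' @export
select_candidates <- function(potential, known, table,
                              min_partners = 3, min_score = 0.9) {
  if (is.data.frame(potential)) potential <- potential$gene
  potential <- as.character(potential)
  known <- unique(as.character(known))
  stopifnot(inherits(table, "score_table"))
  if (min_partners < 1) stop("min_partners must be >= 1")
  if (min_score < 0 || min_score > 1) stop("min_score must be in [0, 1]")

  qual <- table[table$score >= min_score &
                  table$known_gene %in% known &
                  table$potential_gene %in% potential, , drop = FALSE]
  counts <- table(factor(qual$potential_gene, levels = potential))
  keep <- potential[counts[potential] >= min_partners]

  qual <- qual[qual$potential_gene %in% keep, , drop = FALSE]
  qual <- qual[order(match(qual$potential_gene, potential), -qual$score,
                     qual$known_gene), , drop = FALSE]
  partner_str <- vapply(keep, function(g) {
    sub <- qual[qual$potential_gene == g, ]
    paste(paste0(sub$known_gene, ":", format(sub$score, trim = TRUE)),
          collapse = ";")
  }, character(1))

  out <- data.frame(
    candidate = keep,
    n_partners = as.integer(counts[keep]),
    partners = unname(partner_str),
    stringsAsFactors = FALSE, row.names = NULL
  )
  edges <- data.frame(candidate = qual$potential_gene,
                      known_gene = qual$known_gene,
                      score = qual$score,
                      stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "edges") <- edges
  out
}
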