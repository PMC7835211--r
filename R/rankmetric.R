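#' Directional significance score for ranking genes
#'
#' s_g = sign(log2FC_g) * (-log10(max(p_g, p_floor))): up-regulated genes get
#' positive scores that grow with significance, down-regulated genes the
#' mirror image, so sorting by s runs from most up-regulated to most
#' down-regulated. The score is 0 when log2FC = 0 or p = 1.
#'
#' The literal variant `sign(log2FC) / log10(p)` is available for audit via
#' `literal = TRUE`; it induces a non-monotone ordering (more significant
#' genes score closer to zero) and is not used by any downstream stage.
#'
#' @param de [de_table()].
#' @param p_floor lower bound applied to p before taking logs (guards
#'   underflowed p-values); default 1e-300.
#' @param literal use the literal sign/log10(p) variant.
#' @return data.frame with columns `gene_id`, `score`.
#' @export
score_genes <- function(de, p_floor = 1e-300, literal = FALSE) {
  stopifnot(inherits(de, "de_table"))
  if (any(de$p <= 0)) stop("p-values must be > 0; floor upstream zeros")
  p <- pmax(de$p, p_floor)
  s <- if (literal) {
    ifelse(de$p == 1, 0, sign(de$log2fc) / log10(p))
  } else {
    sign(de$log2fc) * (-log10(p))
  }
  data.frame(gene_id = de$gene_id, score = s, stringsAsFactors = FALSE)
}

#' Rank scored genes and map ranks to the centered unit interval
#'
#' Rank N goes to the largest score (most up-regulated), rank 1 to the
#' smallest; ties receive the average of their rank range. The scaled rank is
#' r_g = (rank - (N+1)/2) / N, lying in (-0.5, 0.5) and summing to zero
#' exactly (tie-averaging preserves the sum).
#'
#' @param scored data.frame with `gene_id` and `score` (from
#'   [score_genes()]).
#' @return data.frame of class `ranked_profile` with columns `gene_id`,
#'   `score`, `rank`, `scaled_rank`.
#' @export
rank_profile <- function(scored) {
  stopifnot(all(c("gene_id", "score") %in% names(scored)))
  n <- nrow(scored)
  if (n < 2) stop("need at least 2 genes to rank")
  r <- rank(scored$score, ties.method = "average")
  out <- data.frame(gene_id = scored$gene_id, score = scored$score,
                    rank = r, scaled_rank = (r - (n + 1) / 2) / n,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_profile", "data.frame")
  out
}

#' Write a ranked profile to TSV
#' @param profile [rank_profile()] output.
#' @param path output path.
#' @export
write_ranked_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ranked_profile"))
  # ties serialize in lexicographic gene order for reproducibility
  o <- order(-profile$score, profile$gene_id)
  tab <- as.data.frame(profile)[o, ]
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked profile from TSV
#' @param path TSV with columns gene_id, score, rank, scaled_rank.
#' @return `ranked_profile` data.frame.
#' @export
read_ranked_profile <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("gene_id", "score", "rank", "scaled_rank"))
    if (!col %in% names(tab)) stop(sprintf("missing required column '%s'", col))
  tab$gene_id <- normalize_gene_ids(tab$gene_id)
  if (anyDuplicated(tab$gene_id)) stop("duplicated gene ID in ranked profile")
  class(tab) <- c("ranked_profile", "data.frame")
  tab
}
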