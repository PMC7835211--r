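#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene IDs. Names must be
#'   unique and every set non-empty. Gene IDs are upper-cased (HGNC symbol
#'   convention) so they match expression tables ingested the same way.
#' @param descriptions optional character vector, one per set (GMT column 2).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop(sprintf("duplicate set name: %s",
                 paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", ")))
  sets <- lapply(sets, function(g) unique(normalize_gene_ids(g)))
  if (any(lengths(sets) == 0)) stop("every gene set must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  if (length(descriptions) != length(sets))
    stop("descriptions must have one entry per set")
  structure(sets, descriptions = stats::setNames(as.character(descriptions),
                                                 names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %s\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated MSigDB distribution format: one set per line with
#' fields name, description, then one or more gene symbols. Duplicate genes
#' within a line are collapsed; line order is preserved; malformed lines are
#' rejected with their line number.
#'
#' @param path path to a GMT file.
#' @return [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(stats::setNames(list(), character(0)),
                                                 character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                 bad[1], length(fields[[bad[1]]])))
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop(sprintf("duplicate set name in GMT: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  desc <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection as GMT
#'
#' Round-trips with [read_gmt()].
#' @param gsc [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  desc <- attr(gsc, "descriptions")
  lines <- vapply(names(gsc), function(nm)
    paste(c(nm, desc[[nm]], gsc[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a count matrix and its design table
#'
#' The counts file is tab-separated with a `gene_id` first column and one
#' column per sample; the design file is two tab-separated columns
#' (`sample`, `group`). Samples are reordered to follow the design. Malformed
#' input (non-integer or negative counts, sample mismatch) is rejected.
#'
#' @param path counts TSV path.
#' @param design_path design TSV path.
#' @return [count_matrix()].
#' @export
read_counts <- function(path, design_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(tab) >= 2) stop("counts table must have a gene_id column plus samples")
  gene <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat) || any(is.na(mat)))
    stop("counts must be numeric with no missing values")
  if (any(mat < 0)) stop("validation error: negative count entries")
  if (any(mat != round(mat))) stop("validation error: non-integer count entries")
  rownames(mat) <- gene
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(design)))
    stop("design must have columns 'sample' and 'group'")
  count_matrix(mat, design)
}

#' Write a count matrix and design to TSV
#'
#' @param cm [count_matrix()].
#' @param path counts output path (gene_id + one column per sample).
#' @param design_path design output path (sample, group).
#' @export
write_counts <- function(cm, path, design_path) {
  stopifnot(inherits(cm, "count_matrix"))
  out <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a differential-expression table
#'
#' The interchange object between the DE and enrichment stages: one row per
#' gene with the log2 fold change, the raw p-value and its Benjamini-Hochberg
#' adjustment. If `fdr` is omitted it is recomputed from `p`.
#'
#' @param gene_id unique gene identifiers (upper-cased on ingestion).
#' @param log2fc finite log2 fold changes.
#' @param p raw p-values in (0, 1].
#' @param fdr optional BH-adjusted p-values; recomputed when NULL.
#' @param ave_expr optional average log2-CPM.
#' @return data.frame of class `de_table`.
#' @export
de_table <- function(gene_id, log2fc, p, fdr = NULL, ave_expr = NULL) {
  gene_id <- normalize_gene_ids(gene_id)
  if (anyDuplicated(gene_id))
    stop(sprintf("duplicated gene ID in DE table: %s",
                 paste(unique(gene_id[duplicated(gene_id)]), collapse = ", ")))
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p must lie in (0, 1] with no missing values")
  if (is.null(fdr)) fdr <- bh_adjust(p)
  out <- data.frame(gene_id = gene_id, log2fc = as.numeric(log2fc),
                    p = as.numeric(p), fdr = as.numeric(fdr),
                    stringsAsFactors = FALSE)
  if (!is.null(ave_expr)) out$ave_expr <- as.numeric(ave_expr)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Read a differential-expression table from TSV
#'
#' Requires columns `gene_id`, `log2fc`, `p` (header names); `fdr` and
#' `ave_expr` are optional, with `fdr` recomputed by BH when absent.
#' Duplicate gene IDs and p-values outside (0, 1] are rejected: resolution of
#' duplicates belongs to the join stage, and the ranking score is undefined
#' for missing p.
#'
#' @param path TSV path.
#' @return [de_table()].
#' @export
read_de_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("gene_id", "log2fc", "p"))
    if (!col %in% names(tab)) stop(sprintf("missing required column '%s'", col))
  de_table(tab$gene_id, tab$log2fc, tab$p,
           fdr = if ("fdr" %in% names(tab)) tab$fdr else NULL,
           ave_expr = if ("ave_expr" %in% names(tab)) tab$ave_expr else NULL)
}

#' Write a differential-expression table to TSV
#'
#' Values are serialized at full double precision so a write/read cycle is an
#' identity.
#' @param de [de_table()].
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  stopifnot(inherits(de, "de_table"))
  tab <- as.data.frame(de)
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth tables from a simulation
#'
#' @param truth `ground_truth` object.
#' @param path output TSV path for the per-gene table; the per-set table goes
#'   to `sets_path`.
#' @param sets_path output TSV path for per-set labels.
#' @export
write_truth <- function(truth, path, sets_path) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.table(truth$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$sets, sets_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Every CLI flag has a configuration twin; on conflict the CLI wins.
#'
#' @param path config path.
#' @return named character vector.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop(sprintf("malformed config line (expected key = value): '%s'",
                 lines[which(bad)[1]]))
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  if (anyDuplicated(keys))
    stop(sprintf("duplicate config key: %s",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  stats::setNames(vals, keys)
}
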