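#' Join two differential-expression contrasts into a 2D rank space
#'
#' Restricts both tables to their common gene universe, recomputes the
#' directional significance score and the centered scaled rank within that
#' universe for each contrast, and returns one row per gene with coordinates
#' (r1, r2), each in (-0.5, 0.5). Duplicate gene IDs within a table are
#' resolved by keeping the row with the smallest p (the most informative
#' measurement), with a logged message per gene.
#'
#' @param de1,de2 [de_table()] objects (contrast 1 and contrast 2).
#' @param p_floor passed to [score_genes()].
#' @return data.frame of class `joint_rank_table` with columns `gene_id`,
#'   `s1`, `s2`, `r1`, `r2`.
#' @export
join_contrasts <- function(de1, de2, p_floor = 1e-300) {
  de1 <- resolve_duplicates(de1, "de1")
  de2 <- resolve_duplicates(de2, "de2")
  universe <- intersect(de1$gene_id, de2$gene_id)
  if (length(universe) < 10)
    stop(sprintf("gene universe of the join has %d genes; need >= 10",
                 length(universe)))
  sub1 <- de1[match(universe, de1$gene_id), ]
  sub2 <- de2[match(universe, de2$gene_id), ]
  rp1 <- rank_profile(score_genes(sub1, p_floor = p_floor))
  rp2 <- rank_profile(score_genes(sub2, p_floor = p_floor))
  out <- data.frame(gene_id = universe,
                    s1 = rp1$score, s2 = rp2$score,
                    r1 = rp1$scaled_rank, r2 = rp2$scaled_rank,
                    stringsAsFactors = FALSE)
  class(out) <- c("joint_rank_table", "data.frame")
  out
}

resolve_duplicates <- function(de, label) {
  if (inherits(de, "de_table") && !anyDuplicated(de$gene_id)) return(de)
  stopifnot(all(c("gene_id", "log2fc", "p") %in% names(de)))
  de$gene_id <- normalize_gene_ids(de$gene_id)
  dup <- unique(de$gene_id[duplicated(de$gene_id)])
  if (length(dup)) {
    for (g in dup)
      message(sprintf("join_contrasts: %s has duplicate rows for %s; keeping smallest p",
                      label, g))
    o <- order(de$gene_id, de$p)
    de <- de[o, ][!duplicated(de$gene_id[o]), ]
  }
  de_table(de$gene_id, de$log2fc, de$p)
}

#' Per-dimension enrichment scores of a set in the joint rank space
#'
#' s_d = 2 * mean(scaled rank of members in dimension d); the factor 2 gives
#' the score a portable interpretation: a set occupying the extreme top-k
#' flank reaches (N - k)/N regardless of N. `s_dist` is the Euclidean norm of
#' the pair.
#'
#' @param joint `joint_rank_table` from [join_contrasts()].
#' @param member_ids gene IDs of the set.
#' @return list with `s1`, `s2`, `s_dist`, `size` (members present), or NULL
#'   (with a logged reason) when fewer than 2 members are present.
#' @export
set_scores_2d <- function(joint, member_ids) {
  idx <- joint$gene_id %in% normalize_gene_ids(member_ids)
  k <- sum(idx)
  if (k < 2) {
    message(sprintf("set_scores_2d: only %d member(s) present; set skipped", k))
    return(NULL)
  }
  if (k >= nrow(joint)) stop("set must not cover the whole universe")
  s1 <- 2 * mean(joint$r1[idx])
  s2 <- 2 * mean(joint$r2[idx])
  list(s1 = s1, s2 = s2, s_dist = sqrt(s1^2 + s2^2), size = k)
}

#' Two-group MANOVA of scaled ranks for one gene set
#'
#' Tests whether the set's mean position in the (r1, r2) plane differs from
#' the rest of the universe: a one-way two-group MANOVA on the bivariate
#' scaled ranks, members versus non-members. With two groups, Pillai's trace
#' is an exact monotone transform of Hotelling's T^2,
#' \deqn{T^2 = \frac{k(N-k)}{N} \bar d' S^{-1} \bar d, \quad
#'       V = \frac{T^2}{T^2 + N - 2}, \quad
#'       F = \frac{T^2 (N-3)}{2 (N-2)} \sim F_{2, N-3},}
#' where d-bar is the difference of group mean rank vectors and S the pooled
#' within-group covariance.
#'
#' @param joint `joint_rank_table`.
#' @param member_ids gene IDs of the set; requires 2 <= k and N - k >= 3.
#' @return list with `pillai`, `T2`, `F_stat`, `df_num`, `df_den`, `p`.
#' @export
manova_rank_test <- function(joint, member_ids) {
  idx <- joint$gene_id %in% normalize_gene_ids(member_ids)
  k <- sum(idx); N <- nrow(joint)
  if (k < 2) stop("need at least 2 set members present in the universe")
  if (N - k < 3) stop("need at least 3 non-members")
  X <- cbind(joint$r1, joint$r2)
  for (d in 1:2) {
    if (stats::var(X[, d]) == 0)
      stop(sprintf("rank dimension %d is constant; pooled covariance singular", d))
  }
  Xm <- X[idx, , drop = FALSE]; Xn <- X[!idx, , drop = FALSE]
  d_bar <- colMeans(Xm) - colMeans(Xn)
  Sm <- crossprod(sweep(Xm, 2, colMeans(Xm)))
  Sn <- crossprod(sweep(Xn, 2, colMeans(Xn)))
  S <- (Sm + Sn) / (N - 2)
  rc <- rcond(S)
  if (!is.finite(rc) || rc < .Machine$double.eps * 100) {
    degen <- if (S[1, 1] <= S[2, 2]) 1L else 2L
    stop(sprintf("pooled covariance is singular (rank dimension %d degenerate)", degen))
  }
  T2 <- (k * (N - k) / N) * drop(crossprod(d_bar, solve(S, d_bar)))
  F_stat <- T2 * (N - 3) / (2 * (N - 2))
  list(pillai = T2 / (T2 + N - 2), T2 = T2, F_stat = F_stat,
       df_num = 2, df_den = N - 3,
       p = stats::pf(F_stat, 2, N - 3, lower.tail = FALSE))
}

#' 2D rank enrichment over a gene-set collection
#'
#' Applies [set_scores_2d()] and [manova_rank_test()] to every set with at
#' least `min_size` members in the joint universe, adjusts the MANOVA
#' p-values by Benjamini-Hochberg across exactly the tested sets, and sorts
#' by p (ties by set name).
#'
#' @param joint `joint_rank_table` from [join_contrasts()].
#' @param sets [gene_set_collection()].
#' @param min_size minimum post-intersection set size (default 10; small sets
#'   make the F approximation on ranks fragile).
#' @return data.frame of class `enrich2d_result` with columns `set_name`,
#'   `size`, `s1`, `s2`, `s_dist`, `pillai`, `F_stat`, `df_num`, `df_den`,
#'   `p`, `fdr`; attribute `skipped` lists excluded sets.
#' @export
enrich2d_all <- function(joint, sets, min_size = 10) {
  stopifnot(inherits(joint, "joint_rank_table"),
            inherits(sets, "gene_set_collection"))
  N <- nrow(joint)
  sizes <- vapply(sets, function(g) sum(joint$gene_id %in% g), 0L)
  keep <- sizes >= min_size & (N - sizes) >= 3
  skipped <- sprintf("%s: %d members in universe (min_size %d)",
                     names(sets)[!keep], sizes[!keep], as.integer(min_size))
  for (msg in skipped) message("enrich2d_all: skipping ", msg)
  if (!any(keep)) stop("no gene set passed the size filter")
  nm <- names(sets)[keep]
  rows <- lapply(nm, function(s) {
    sc <- set_scores_2d(joint, sets[[s]])
    mv <- manova_rank_test(joint, sets[[s]])
    data.frame(set_name = s, size = sc$size, s1 = sc$s1, s2 = sc$s2,
               s_dist = sc$s_dist, pillai = mv$pillai, F_stat = mv$F_stat,
               df_num = mv$df_num, df_den = mv$df_den, p = mv$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p)
  res <- res[order(res$p, res$set_name), ]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  class(res) <- c("enrich2d_result", "data.frame")
  res
}

#' Bin the joint rank space into a density grid
#'
#' Equal-width bins spanning [-0.5, 0.5] on each axis, half-open [lo, hi)
#' except the last bin which is closed; every gene falls in exactly one cell,
#' so the grid sums to N. Rows index r1 (x, ascending), columns r2 (y,
#' ascending). This is the object a filled-contour rank-rank plot displays.
#'
#' @param joint `joint_rank_table`.
#' @param bins bins per axis (>= 1).
#' @return integer matrix `bins x bins` with bin-center dimnames.
#' @export
density_grid <- function(joint, bins = 50) {
  stopifnot(inherits(joint, "joint_rank_table"))
  bins <- as.integer(bins)
  if (bins < 1) stop("bins must be >= 1")
  breaks <- seq(-0.5, 0.5, length.out = bins + 1)
  ix <- findInterval(joint$r1, breaks, rightmost.closed = TRUE)
  iy <- findInterval(joint$r2, breaks, rightmost.closed = TRUE)
  centers <- sprintf("%.6g", (breaks[-1] + breaks[-(bins + 1)]) / 2)
  grid <- matrix(0L, bins, bins, dimnames = list(r1 = centers, r2 = centers))
  for (g in seq_along(ix)) grid[ix[g], iy[g]] <- grid[ix[g], iy[g]] + 1L
  grid
}

#' Write an enrichment result or density grid to TSV
#' @param x `enrich2d_result` data.frame or a matrix from [density_grid()].
#' @param path output path.
#' @export
write_enrich2d <- function(x, path) {
  if (is.matrix(x)) {
    out <- data.frame(r1 = rownames(x), x, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
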