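# ES of a member-position vector, classic (unweighted) mode.
# Walking the ranked list, the running sum rises by 1/Nh at members and falls
# by 1/(N-Nh) elsewhere; candidate maxima sit at hit positions and candidate
# minima immediately before them, so the extremum is computable in O(Nh).
# All comparisons are done on the walk scaled by Nh*(N-Nh): integer-valued,
# hence exact, so ties resolve deterministically.
es_from_positions <- function(hits, N) {
  nh <- length(hits)
  miss <- N - nh
  i <- seq_len(nh)
  after <- i * miss - (hits - i) * nh    # scaled value right after hit i
  before <- after - miss                 # scaled value right before hit i
  scale <- nh * miss
  max_i <- which.max(after)
  min_i <- which.min(before)
  max_val <- after[max_i]
  min_val <- before[min_i]
  pos_max <- hits[max_i]
  pos_min <- hits[min_i] - 1L
  if (max_val > -min_val) {
    list(es = max_val / scale, position = pos_max, lead_idx = seq_len(max_i))
  } else if (-min_val > max_val) {
    list(es = min_val / scale, position = pos_min, lead_idx = seq.int(min_i, nh))
  } else if (max_val == 0) {
    list(es = 0, position = NA_integer_, lead_idx = integer(0))
  } else {
    # equal-magnitude deviations: take the one encountered first in the walk
    message(sprintf("running_es: tie at extremum (|ES| = %.6g); taking the earlier deviation", max_val / scale))
    if (pos_max <= pos_min)
      list(es = max_val / scale, position = pos_max, lead_idx = seq_len(max_i))
    else
      list(es = min_val / scale, position = pos_min, lead_idx = seq.int(min_i, nh))
  }
}

#' Classic-mode running enrichment score
#'
#' Kolmogorov-Smirnov-style walk over a ranked gene list: from the most
#' up-regulated gene to the most down-regulated, the running sum increases by
#' 1/Nh at set members and decreases by 1/(N - Nh) at non-members. The
#' enrichment score is the deviation of largest magnitude; the leading edge is
#' the members at or before the maximum (positive ES) or at or after the
#' minimum (negative ES). Equal-magnitude positive and negative deviations are
#' resolved in favour of the one encountered first, with a logged message.
#'
#' @param ranked_ids gene IDs ordered by decreasing score (no duplicates).
#' @param member_ids gene IDs of the set; genes absent from `ranked_ids` are
#'   ignored (intersection semantics).
#' @return list with `es` (in [-1, 1]), `position` (index of the extremum)
#'   and `leading_edge` (character vector of member IDs).
#' @export
running_es <- function(ranked_ids, member_ids) {
  if (anyDuplicated(ranked_ids)) stop("ranked list must not contain duplicates")
  N <- length(ranked_ids)
  hits <- which(ranked_ids %in% normalize_gene_ids(member_ids))
  nh <- length(hits)
  if (nh == 0) stop("no overlap between set and ranked list")
  if (nh == N) stop("set covers the entire ranked list; ES undefined")
  r <- es_from_positions(hits, N)
  list(es = r$es, position = r$position,
       leading_edge = ranked_ids[hits[r$lead_idx]])
}

#' Running-sum profile of a set over a ranked list
#'
#' The full walk underlying [running_es()], exported as a table for
#' enrichment-style plotting by the caller.
#' @inheritParams running_es
#' @return data.frame with columns `position`, `gene_id`, `is_member`,
#'   `running_sum`.
#' @export
running_sum_profile <- function(ranked_ids, member_ids) {
  N <- length(ranked_ids)
  is_member <- ranked_ids %in% normalize_gene_ids(member_ids)
  nh <- sum(is_member)
  if (nh == 0 || nh == N) stop("set overlap must satisfy 0 < Nh < N")
  step <- ifelse(is_member, N - nh, -nh)  # integer walk, exact in doubles
  data.frame(position = seq_len(N), gene_id = ranked_ids,
             is_member = is_member,
             running_sum = cumsum(step) / (nh * (N - nh)),
             stringsAsFactors = FALSE)
}

#' Pre-ranked gene set enrichment analysis, classic mode
#'
#' For each gene set (restricted to genes present in the profile and to sizes
#' within `[min_size, max_size]`), computes the classic enrichment score and a
#' gene-tag permutation null: `nperm` random same-size member sets drawn from
#' the profile. The nominal p-value is the plus-one-corrected fraction of
#' same-sign null scores at least as extreme; NES divides ES by the mean
#' magnitude of same-sign null scores; the FDR q-value compares, per sign, the
#' fraction of pooled null NES values at least as extreme against the fraction
#' of observed NES values at least as extreme, capped at 1.
#'
#' Sets with no overlap are skipped with a logged reason (see the `skipped`
#' attribute). Results are deterministic given `seed`.
#'
#' @param profile `ranked_profile` (see [rank_profile()]).
#' @param sets [gene_set_collection()].
#' @param min_size,max_size post-intersection size bounds (defaults 10 and
#'   5000, the conventional pre-ranked GSEA bounds).
#' @param nperm number of permutations, >= 100 (default 1000).
#' @param seed RNG seed for the permutation null.
#' @return data.frame of class `gsea_result` with columns `set_name`, `size`,
#'   `es`, `nes`, `p`, `fdr`, `leading_edge` (comma-joined); attribute
#'   `skipped` lists sets excluded and why.
#' @export
gsea_preranked <- function(profile, sets, min_size = 10, max_size = 5000,
                           nperm = 1000, seed = 1L) {
  stopifnot(inherits(profile, "ranked_profile"),
            inherits(sets, "gene_set_collection"))
  if (nperm < 100) stop("nperm must be >= 100")
  o <- order(-profile$score, profile$gene_id)
  ranked <- profile$gene_id[o]
  N <- length(ranked)

  members <- lapply(sets, function(g) which(ranked %in% g))
  sizes <- lengths(members)
  skipped <- character(0)
  drop_zero <- sizes == 0
  if (any(drop_zero)) {
    skipped <- c(skipped, sprintf("%s: no overlap with ranked profile",
                                  names(sets)[drop_zero]))
  }
  out_of_bounds <- !drop_zero & (sizes < min_size | sizes > max_size)
  if (any(out_of_bounds)) {
    skipped <- c(skipped, sprintf("%s: size %d outside [%d, %d]",
                                  names(sets)[out_of_bounds],
                                  sizes[out_of_bounds],
                                  as.integer(min_size), as.integer(max_size)))
  }
  for (msg in skipped) message("gsea_preranked: skipping ", msg)
  keep <- which(!drop_zero & !out_of_bounds)
  if (!length(keep)) stop("no gene set passed the size filter")
  if (any(sizes[keep] == N))
    stop("a set covers the entire ranked list; ES undefined")

  with_seed(seed, {
    # permutation null shared across sets of equal size (gene-tag null
    # depends on size only)
    uniq_sizes <- sort(unique(sizes[keep]))
    null_es <- lapply(uniq_sizes, function(k) {
      vapply(seq_len(nperm), function(i)
        es_from_positions(sort.int(sample.int(N, k)), N)$es, 0)
    })
    names(null_es) <- as.character(uniq_sizes)

    res <- data.frame(set_name = names(sets)[keep],
                      size = unname(sizes[keep]),
                      es = NA_real_, nes = NA_real_, p = NA_real_,
                      fdr = NA_real_, leading_edge = "",
                      stringsAsFactors = FALSE)
    null_nes_pool <- vector("list", nrow(res))
    for (i in seq_len(nrow(res))) {
      idx <- keep[i]
      r <- es_from_positions(members[[idx]], N)
      res$es[i] <- r$es
      res$leading_edge[i] <- paste(ranked[members[[idx]][r$lead_idx]],
                                   collapse = ",")
      nul <- null_es[[as.character(sizes[idx])]]
      same <- if (r$es >= 0) nul[nul >= 0] else nul[nul < 0]
      if (!length(same)) {
        message(sprintf(
          "gsea_preranked: no same-sign null values for %s; p and NES unavailable",
          res$set_name[i]))
        null_nes_pool[[i]] <- numeric(0)
        next
      }
      res$p[i] <- (1 + sum(abs(same) >= abs(r$es))) / (1 + length(same))
      denom <- mean(abs(same))
      res$nes[i] <- r$es / denom
      # same-size null scores on the NES scale, for the pooled FDR
      pos <- nul >= 0
      nes_null <- numeric(length(nul))
      if (any(pos)) nes_null[pos] <- nul[pos] / mean(nul[pos])
      if (any(!pos)) nes_null[!pos] <- nul[!pos] / mean(abs(nul[!pos]))
      null_nes_pool[[i]] <- nes_null
    }

    pool <- unlist(null_nes_pool)
    pos_pool <- pool[pool >= 0]; neg_pool <- pool[pool < 0]
    obs <- res$nes
    for (i in seq_len(nrow(res))) {
      if (is.na(obs[i])) next
      if (obs[i] >= 0) {
        num <- if (length(pos_pool)) mean(pos_pool >= obs[i]) else 0
        den <- mean(obs[!is.na(obs) & obs >= 0] >= obs[i])
      } else {
        num <- if (length(neg_pool)) mean(neg_pool <= obs[i]) else 0
        den <- mean(obs[!is.na(obs) & obs < 0] <= obs[i])
      }
      res$fdr[i] <- min(1, num / den)
    }
    res <- res[order(res$p, res$set_name), ]
    rownames(res) <- NULL
    attr(res, "skipped") <- skipped
    class(res) <- c("gsea_result", "data.frame")
    res
  })
}

#' Write a GSEA result table to TSV
#' @param res `gsea_result` from [gsea_preranked()].
#' @param path output path.
#' @export
write_gsea_result <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
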