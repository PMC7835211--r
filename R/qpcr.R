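#' Construct a Ct (quantification cycle) table
#'
#' One row per (sample, target) measurement with the sample's group label.
#' @param sample_id sample identifiers.
#' @param group group labels (e.g. LG, LGV, HG, HGV).
#' @param target target gene per row.
#' @param ct quantification cycle, > 0 and finite.
#' @param replicate optional replicate index.
#' @return data.frame of class `ct_table`.
#' @export
ct_table <- function(sample_id, group, target, ct, replicate = NULL) {
  if (any(!is.finite(ct)) || any(ct <= 0))
    stop("Ct values must be finite and > 0")
  out <- data.frame(sample_id = as.character(sample_id),
                    group = as.character(group),
                    target = as.character(target),
                    ct = as.numeric(ct), stringsAsFactors = FALSE)
  if (!is.null(replicate)) out$replicate <- replicate
  if (anyDuplicated(out[c("sample_id", "target")]))
    stop("duplicate (sample, target) measurement")
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Read a Ct table from TSV
#' @param path TSV with columns sample_id, group, target, ct (replicate
#'   optional).
#' @return [ct_table()].
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group", "target", "ct"))
    if (!col %in% names(tab)) stop(sprintf("missing required column '%s'", col))
  ct_table(tab$sample_id, tab$group, tab$target, tab$ct,
           replicate = if ("replicate" %in% names(tab)) tab$replicate else NULL)
}

#' Comparative Ct relative quantification (2^-ddCt)
#'
#' Per sample and target: dCt = Ct_target - Ct_reference;
#' ddCt = dCt - mean(dCt over the calibrator group);
#' RQ = 2^-ddCt. Assumes an amplification efficiency of 2 per cycle (the
#' comparative-Ct assumption). By construction the calibrator group's RQ
#' values have geometric mean 1.
#'
#' @param ct [ct_table()].
#' @param reference_target name of the normalizer gene (must be measured in
#'   every sample that has a target measurement).
#' @param calibrator_group group whose mean dCt anchors ddCt (must be
#'   non-empty for every target).
#' @return data.frame with columns `sample_id`, `group`, `target`,
#'   `delta_ct`, `delta_delta_ct`, `rq`.
#' @export
relative_quantification <- function(ct, reference_target, calibrator_group) {
  stopifnot(inherits(ct, "ct_table"))
  ref <- ct[ct$target == reference_target, ]
  if (!nrow(ref)) stop(sprintf("reference target '%s' not measured", reference_target))
  tgt <- ct[ct$target != reference_target, ]
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  missing <- !(tgt$sample_id %in% names(ref_ct))
  if (any(missing)) {
    bad <- tgt[which(missing)[1], ]
    stop(sprintf("missing reference measurement for sample '%s' (target '%s')",
                 bad$sample_id, bad$target))
  }
  tgt$delta_ct <- tgt$ct - ref_ct[tgt$sample_id]
  out <- do.call(rbind, lapply(split(tgt, tgt$target), function(d) {
    cal <- d$delta_ct[d$group == calibrator_group]
    if (!length(cal))
      stop(sprintf("calibrator group '%s' is empty for target '%s'",
                   calibrator_group, d$target[1]))
    d$delta_delta_ct <- d$delta_ct - mean(cal)
    d$rq <- 2 ^ (-d$delta_delta_ct)
    d
  }))
  rownames(out) <- NULL
  out[c("sample_id", "group", "target", "delta_ct", "delta_delta_ct", "rq")]
}

#' ChIP-qPCR enrichment as percent of input
#'
#' Adjusts the input Ct for the fraction of chromatin it represents,
#' Ct' = Ct_input - log2(1 / input_fraction), then
#' percent input = 100 * 2^(Ct' - Ct_IP). With perfect efficiency, an IP one
#' cycle lower doubles the recovered fraction.
#'
#' @param ct_ip Ct of the immunoprecipitated sample(s).
#' @param ct_input Ct of the matched input(s).
#' @param input_fraction fraction of chromatin used as input, in (0, 1];
#'   required explicitly (no hidden dilution default).
#' @return percent of input (vectorized).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (length(input_fraction) != 1 || !is.finite(input_fraction) ||
      input_fraction <= 0 || input_fraction > 1)
    stop("input_fraction must be a single value in (0, 1]")
  if (any(!is.finite(ct_ip)) || any(!is.finite(ct_input)))
    stop("Ct values must be finite")
  ct_adj <- ct_input - log2(1 / input_fraction)
  100 * 2 ^ (ct_adj - ct_ip)
}

#' One-way ANOVA of RQ across groups (convenience)
#'
#' Thin wrapper over `stats::aov` for the per-target group comparison shown
#' on qPCR bar plots; not part of the enrichment pipeline.
#' @param rq output of [relative_quantification()].
#' @return data.frame with columns `target`, `F_stat`, `p`.
#' @export
rq_anova <- function(rq) {
  do.call(rbind, lapply(split(rq, rq$target), function(d) {
    fit <- stats::anova(stats::aov(rq ~ group, data = d))
    data.frame(target = d$target[1], F_stat = fit$`F value`[1],
               p = fit$`Pr(>F)`[1], stringsAsFactors = FALSE)
  }))
}
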