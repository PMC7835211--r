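#' Specification for a default block of simulated gene sets
#'
#' One row per stratum of gene sets: `n_sets` disjoint sets of `set_size`
#' genes whose members receive a coordinated expression shift of
#' `delta_glucose` log2 units under high glucose (groups HG and HGV) and a
#' further `delta_vpa` log2 units under VPA on top of high glucose (group
#' HGV). Rows with both deltas zero describe null sets.
#'
#' The default emulates the headline biology: a handful of pathways induced
#' by hyperglycaemia and attenuated by the HDAC inhibitor (delta pair
#' +1.5/-1.5, 50 genes each) embedded among null sets of mixed sizes.
#'
#' @return data.frame with columns `set_size`, `n_sets`, `delta_glucose`,
#'   `delta_vpa`.
#' @export
default_set_specs <- function() {
  data.frame(
    set_size      = c(50,  20, 50, 100),
    n_sets        = c(5,   10, 10,  10),
    delta_glucose = c(1.5,  0,  0,   0),
    delta_vpa     = c(-1.5, 0,  0,   0)
  )
}

#' Configuration for the synthetic RNA-seq experiment
#'
#' Describes a 2-factor (glucose level x VPA treatment), 4-group experiment
#' with `n_reps` replicates per group, mirroring a hepatocyte culture design:
#' low glucose (LG), low glucose + VPA (LGV), high glucose (HG) and high
#' glucose + VPA (HGV). Counts are negative binomial with mean `lambda_g`
#' (log-normal across genes) and variance `lambda + phi * lambda^2`, where the
#' per-gene dispersion follows the decreasing trend
#' `phi_g = dispersion_asymptote + dispersion_slope / lambda_g` commonly seen
#' in RNA-seq. Per-sample library-size factors are log-normal with coefficient
#' of variation `libsize_cv` and enter through the NB mean, so the count
#' distribution stays negative binomial.
#'
#' @param n_genes number of genes simulated.
#' @param n_reps replicates per group (>= 2).
#' @param groups ordered group labels; the first is the untreated
#'   normoglycemic reference, third/fourth carry the glucose and glucose+VPA
#'   effects.
#' @param baseline_log2_mean_mu,baseline_log2_mean_sd mean and sd of the
#'   per-gene baseline log2 expected count.
#' @param dispersion_asymptote,dispersion_slope parameters of the
#'   mean-dispersion trend (both >= 0); asymptote 0.05 corresponds to a
#'   biological coefficient of variation of ~0.22 for abundant genes.
#' @param libsize_cv coefficient of variation of library-size factors.
#' @param set_specs data.frame as in [default_set_specs()].
#' @param frac_dropout_members fraction of each planted set's members that
#'   receive no effect (truth records 0 for them).
#' @param vpa_affects_lg if TRUE the LGV group receives the same VPA shift as
#'   HGV; the default leaves the normoglycemic VPA response at zero since it
#'   is a free parameter of the design.
#' @param overlapping_sets if FALSE (default) set memberships are sampled
#'   disjointly, which keeps the ground truth unambiguous.
#' @param seed integer RNG seed; identical seed and configuration give
#'   bit-identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000, n_reps = 3,
                       groups = c("LG", "LGV", "HG", "HGV"),
                       baseline_log2_mean_mu = 5,
                       baseline_log2_mean_sd = 2,
                       dispersion_asymptote = 0.05,
                       dispersion_slope = 2,
                       libsize_cv = 0.2,
                       set_specs = default_set_specs(),
                       frac_dropout_members = 0,
                       vpa_affects_lg = FALSE,
                       overlapping_sets = FALSE,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
              groups = as.character(groups),
              baseline_log2_mean_mu = baseline_log2_mean_mu,
              baseline_log2_mean_sd = baseline_log2_mean_sd,
              dispersion_asymptote = dispersion_asymptote,
              dispersion_slope = dispersion_slope,
              libsize_cv = libsize_cv,
              set_specs = set_specs,
              frac_dropout_members = frac_dropout_members,
              vpa_affects_lg = isTRUE(vpa_affects_lg),
              overlapping_sets = isTRUE(overlapping_sets),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_genes) || cfg$n_genes < 2)
    stop_config("n_genes", "must be a count >= 2")
  if (is.na(cfg$n_reps) || cfg$n_reps < 2)
    stop_config("n_reps", "must be >= 2")
  if (length(cfg$groups) != 4 || anyDuplicated(cfg$groups))
    stop_config("groups", "must be 4 unique labels (reference, ref+VPA, glucose, glucose+VPA)")
  if (cfg$dispersion_asymptote < 0)
    stop_config("dispersion_asymptote", "must be >= 0")
  if (cfg$dispersion_slope < 0)
    stop_config("dispersion_slope", "must be >= 0")
  if (cfg$libsize_cv < 0)
    stop_config("libsize_cv", "must be >= 0")
  if (cfg$frac_dropout_members < 0 || cfg$frac_dropout_members >= 1)
    stop_config("frac_dropout_members", "must be in [0, 1)")
  ss <- cfg$set_specs
  need <- c("set_size", "n_sets", "delta_glucose", "delta_vpa")
  if (!is.data.frame(ss) || !all(need %in% names(ss)))
    stop_config("set_specs", paste("must be a data.frame with columns",
                                   paste(need, collapse = ", ")))
  if (nrow(ss) > 0) {
    if (any(ss$set_size < 2) || any(ss$set_size >= cfg$n_genes))
      stop_config("set_specs", "set sizes must be >= 2 and < n_genes")
    if (any(!is.finite(ss$delta_glucose)) || any(!is.finite(ss$delta_vpa)))
      stop_config("set_specs", "all deltas must be finite")
    if (any(ss$n_sets < 0))
      stop_config("set_specs", "n_sets must be >= 0")
    if (!cfg$overlapping_sets && sum(ss$set_size * ss$n_sets) > cfg$n_genes)
      stop_config("set_specs", "disjoint sets require sum(set_size * n_sets) <= n_genes")
  }
  if (is.na(cfg$seed)) stop_config("seed", "must be an integer")
  invisible(cfg)
}

#' Construct a validated count matrix object
#'
#' @param counts non-negative integer matrix, genes x samples, with rownames
#'   (gene IDs) and colnames (sample IDs).
#' @param design data.frame with columns `sample` and `group` covering every
#'   column of `counts`.
#' @return object of class `count_matrix`: list with `counts` and `design`.
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  rownames(counts) <- normalize_gene_ids(rownames(counts))
  if (anyDuplicated(rownames(counts)))
    stop("gene IDs must be unique after case normalization")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative with no missing values")
  if (any(counts != round(counts)))
    stop("counts must be integer-valued")
  storage.mode(counts) <- "integer"
  design <- data.frame(sample = as.character(design$sample),
                       group = as.character(design$group),
                       stringsAsFactors = FALSE)
  missing <- setdiff(colnames(counts), design$sample)
  extra <- setdiff(design$sample, colnames(counts))
  if (length(missing) || length(extra))
    stop(sprintf("sample mismatch between counts and design: missing from design [%s]; absent from counts [%s]",
                 paste(missing, collapse = ","), paste(extra, collapse = ",")))
  counts <- counts[, design$sample, drop = FALSE]
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$design$group), collapse = ", ")))
  invisible(x)
}

#' Simulate a 2x2 glucose-by-VPA RNA-seq experiment
#'
#' Draws negative-binomial counts for the four-group design described by
#' `config`, plants coordinated log2 fold-change shifts into the gene sets of
#' `config$set_specs`, and returns the count matrix, the gene-set collection,
#' and the ground-truth effect table.
#'
#' Effects are multiplicative on the NB mean: members of a planted set have
#' their HG and HGV means scaled by `2^delta_glucose`, and their HGV mean
#' further scaled by `2^delta_vpa`, so the contrast HG-vs-LG carries
#' `delta_glucose` and HGV-vs-HG carries `delta_vpa`.
#'
#' @param config a [sim_config()] object.
#' @return list with components `counts` ([count_matrix]), `sets`
#'   ([gene_set_collection]) and `truth` (class `ground_truth`).
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    ng <- config$n_genes
    gene_ids <- sprintf("G%06d", seq_len(ng))
    lambda <- 2 ^ stats::rnorm(ng, config$baseline_log2_mean_mu,
                               config$baseline_log2_mean_sd)
    phi <- config$dispersion_asymptote + config$dispersion_slope / lambda

    # assign set memberships
    ss <- config$set_specs
    set_rows <- if (nrow(ss)) rep(seq_len(nrow(ss)), ss$n_sets) else integer(0)
    n_sets <- length(set_rows)
    sets <- vector("list", n_sets)
    set_names <- sprintf("SET%03d", seq_len(n_sets))
    pool <- gene_ids
    lfc_glucose <- stats::setNames(numeric(ng), gene_ids)
    lfc_vpa <- stats::setNames(numeric(ng), gene_ids)
    set_meta <- data.frame(set_name = character(0), size = integer(0),
                           delta_glucose = numeric(0), delta_vpa = numeric(0),
                           label = character(0), stringsAsFactors = FALSE)
    for (i in seq_len(n_sets)) {
      row <- ss[set_rows[i], ]
      members <- if (config$overlapping_sets) {
        sample(gene_ids, row$set_size)
      } else {
        m <- sample(pool, row$set_size)
        pool <- setdiff(pool, m)
        m
      }
      planted <- row$delta_glucose != 0 || row$delta_vpa != 0
      affected <- members
      if (planted && config$frac_dropout_members > 0) {
        nd <- round(config$frac_dropout_members * length(members))
        if (nd > 0) affected <- setdiff(members, sample(members, nd))
      }
      if (planted) {
        lfc_glucose[affected] <- lfc_glucose[affected] + row$delta_glucose
        lfc_vpa[affected] <- lfc_vpa[affected] + row$delta_vpa
      }
      sets[[i]] <- members
      set_meta <- rbind(set_meta, data.frame(
        set_name = set_names[i], size = row$set_size,
        delta_glucose = row$delta_glucose, delta_vpa = row$delta_vpa,
        label = if (planted) "planted" else "null",
        stringsAsFactors = FALSE))
    }
    names(sets) <- set_names
    descriptions <- sprintf("%s|delta_glucose=%g|delta_vpa=%g",
                            set_meta$label, set_meta$delta_glucose,
                            set_meta$delta_vpa)

    # group mean multipliers, genes x groups
    g <- config$groups
    mult <- matrix(1, ng, 4, dimnames = list(gene_ids, g))
    mult[, g[3]] <- 2 ^ lfc_glucose
    mult[, g[4]] <- 2 ^ (lfc_glucose + lfc_vpa)
    if (config$vpa_affects_lg) mult[, g[2]] <- 2 ^ lfc_vpa

    design <- data.frame(
      sample = paste(rep(g, each = config$n_reps),
                     rep(seq_len(config$n_reps), times = 4), sep = "_"),
      group = rep(g, each = config$n_reps), stringsAsFactors = FALSE)
    nsamp <- nrow(design)
    if (config$libsize_cv > 0) {
      sdlog <- sqrt(log(1 + config$libsize_cv^2))
      libfac <- stats::rlnorm(nsamp, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else libfac <- rep(1, nsamp)

    counts <- matrix(0L, ng, nsamp, dimnames = list(gene_ids, design$sample))
    for (j in seq_len(nsamp)) {
      mu <- lambda * mult[, design$group[j]] * libfac[j]
      counts[, j] <- if (all(phi == 0)) stats::rpois(ng, mu) else
        stats::rnbinom(ng, mu = mu, size = 1 / phi)
    }

    truth <- structure(list(
      genes = data.frame(gene_id = gene_ids,
                         true_lfc_glucose = unname(lfc_glucose),
                         true_lfc_vpa = unname(lfc_vpa),
                         stringsAsFactors = FALSE),
      sets = set_meta,
      contrasts = c(glucose = paste(g[3], "vs", g[1], sep = "_"),
                    vpa = paste(g[4], "vs", g[3], sep = "_"))),
      class = "ground_truth")

    list(counts = count_matrix(counts, design),
         sets = gene_set_collection(sets, descriptions),
         truth = truth)
  })
}

#' Extract the table of true log2 fold changes for one contrast
#'
#' @param truth `ground_truth` from [simulate_experiment()].
#' @param contrast one of the two encoded contrast labels, e.g.
#'   `"HG_vs_LG"` or `"HGV_vs_HG"` (also accepted: `"glucose"`, `"vpa"`).
#' @return data.frame with columns `gene_id`, `true_log2fc`.
#' @export
true_contrast_table <- function(truth, contrast) {
  stopifnot(inherits(truth, "ground_truth"))
  key <- if (contrast %in% names(truth$contrasts)) contrast
         else names(truth$contrasts)[match(contrast, truth$contrasts)]
  if (is.na(key) || !length(key))
    stop(sprintf("unknown contrast '%s'; available: %s", contrast,
                 paste(truth$contrasts, collapse = ", ")))
  col <- paste0("true_lfc_", key)
  data.frame(gene_id = truth$genes$gene_id,
             true_log2fc = truth$genes[[col]],
             stringsAsFactors = FALSE)
}
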