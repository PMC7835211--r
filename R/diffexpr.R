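#' Remove genes with low average counts
#'
#' Keeps exactly the genes whose mean count per sample (row sum divided by the
#' number of samples) is at least `threshold`; genes averaging fewer reads
#' than the threshold are omitted from downstream analysis. Row order is
#' preserved and the operation is idempotent.
#'
#' @param cm [count_matrix()].
#' @param threshold minimum mean reads per sample (default 10).
#' @return filtered [count_matrix()].
#' @export
filter_low_expression <- function(cm, threshold = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  if (threshold < 0) stop("threshold must be >= 0")
  keep <- rowMeans(cm$counts) >= threshold
  cm$counts <- cm$counts[keep, , drop = FALSE]
  cm
}

#' Log2 counts-per-million with a pseudo-count
#'
#' value = log2( (count + c) / (libsize + 2c) * 1e6 ), the standard smoothed
#' log-CPM: the pseudo-count keeps zeros finite and the 2c in the denominator
#' keeps values bounded as counts approach the library size. Library sizes are
#' the column sums of the count matrix.
#'
#' @param cm [count_matrix()].
#' @param pseudo_count c > 0 (default 0.5).
#' @return object of class `log_expression`: list with `values` (matrix),
#'   `library_sizes` and `design`.
#' @export
log_cpm <- function(cm, pseudo_count = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (pseudo_count <= 0) stop("pseudo_count must be > 0")
  lib <- colSums(cm$counts)
  if (any(lib <= 0)) stop("library sizes must be > 0")
  vals <- log2(t((t(cm$counts) + pseudo_count) / (lib + 2 * pseudo_count)) * 1e6)
  structure(list(values = vals, library_sizes = lib, design = cm$design),
            class = "log_expression")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min over j >= i of (m * p_(j) / j), capped at 1, returned in the
#' input order.
#'
#' @param p p-values in (0, 1].
#' @return adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(m * p[o] / (m:1)))[order(o)]
}

# Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0),
# needed by the moment-matching prior fit.
trigamma_inverse <- function(x) {
  if (x <= 0) stop("trigamma_inverse requires x > 0")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Estimate the variance prior by moment matching on log variances
#'
#' Fits the scaled inverse-chi-square prior (d0, s0^2) of the moderated t-test
#' from the empirical distribution of per-gene residual variances s^2 on d_g
#' degrees of freedom: on the log scale, E log s^2 and Var log s^2 have closed
#' forms in digamma/trigamma, so d0 solves
#' trigamma(d0/2) = Var(e) - trigamma(d_g/2) with
#' e = log s^2 - digamma(d_g/2) + log(d_g/2); when the empirical variance does
#' not exceed the sampling noise, d0 is infinite and the prior collapses to a
#' point mass. Zero variances are excluded from the fit.
#'
#' @param s2 per-gene residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return list with `prior_df` (d0, possibly Inf) and `prior_var` (s0^2).
#' @export
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) stop("need at least 2 positive variances to fit a prior")
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(prior_df = d0, prior_var = s02)
}

#' Moderated two-group t-test on log-CPM
#'
#' A documented minimal stand-in for the moderated linear-model tests used by
#' mainstream RNA-seq packages: per gene, the log2 fold change is the
#' difference of group means on log-CPM, the pooled residual variance s^2_g
#' (d_g = n_a + n_b - 2 df) is shrunk toward a prior fitted by
#' [estimate_variance_prior()],
#' \deqn{\tilde{s}^2_g = (d_0 s_0^2 + d_g s^2_g) / (d_0 + d_g),}
#' and t = log2FC / (s_tilde * sqrt(1/n_a + 1/n_b)) is referred to a
#' t-distribution on d0 + d_g df (normal in the d0 = Inf limit). FDR is BH.
#'
#' @param logexpr `log_expression` from [log_cpm()].
#' @param group_a control group label (subtrahend of the fold change).
#' @param group_b treatment group label; log2FC = mean(b) - mean(a).
#' @param prior optional list(prior_df, prior_var) to bypass estimation.
#' @return [de_table()] with `ave_expr` (mean log-CPM over both groups) and a
#'   `zero_variance` attribute flagging genes where d0 = 0 met s^2_g = 0.
#' @export
moderated_two_group_test <- function(logexpr, group_a, group_b, prior = NULL) {
  stopifnot(inherits(logexpr, "log_expression"))
  design <- logexpr$design
  ia <- which(design$group == group_a)
  ib <- which(design$group == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop(sprintf("each group needs >= 2 samples (got %s=%d, %s=%d)",
                 group_a, length(ia), group_b, length(ib)))
  xa <- logexpr$values[, design$sample[ia], drop = FALSE]
  xb <- logexpr$values[, design$sample[ib], drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  lfc <- mb - ma
  rss <- rowSums((xa - ma)^2) + rowSums((xb - mb)^2)
  df <- na + nb - 2
  s2 <- rss / df
  if (is.null(prior)) prior <- estimate_variance_prior(s2, df)
  d0 <- prior$prior_df; s02 <- prior$prior_var
  if (s02 <= 0) stop("prior_var must be > 0")
  s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
  zero_var <- d0 == 0 & s2 == 0
  se <- sqrt(s2_tilde * (1 / na + 1 / nb))
  t <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(t), df = d0 + df)
  p[zero_var] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0,1] for downstream scoring
  out <- de_table(rownames(logexpr$values), lfc, p,
                  ave_expr = (na * ma + nb * mb) / (na + nb))
  attr(out, "prior") <- prior
  attr(out, "zero_variance") <- unname(zero_var)
  out
}
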