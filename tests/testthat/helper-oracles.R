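# Independent oracles and small fixture builders shared across test files.

# Brute-force BH step-up: literal q_(i) = min_{j >= i} m p_(j) / j, capped.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force classic-mode ES: materialize the whole running sum and take the
# extremum, first-encountered deviation winning magnitude ties.
es_oracle <- function(ranked, members) {
  is_m <- ranked %in% members
  nh <- sum(is_m)
  N <- length(ranked)
  # integer-step walk (scaled by nh*(N-nh)) keeps extrema and ties exact
  walk <- cumsum(ifelse(is_m, N - nh, -nh)) / (nh * (N - nh))
  i_max <- which.max(walk)
  i_min <- which.min(walk)
  mx <- walk[i_max]
  mn <- walk[i_min]
  if (mx > -mn) es <- mx
  else if (-mn > mx) es <- mn
  else if (mx == 0) es <- 0
  else es <- if (i_max <= i_min) mx else mn
  lead <- if (es > 0) ranked[is_m & seq_len(N) <= i_max]
          else if (es < 0) ranked[is_m & seq_len(N) >= i_min]
          else character(0)
  list(es = es, leading_edge = lead)
}

# Small random DE table with valid p-values.
random_de_table <- function(n, seed) {
  set.seed(seed)
  de_table(sprintf("G%04d", seq_len(n)),
           log2fc = rnorm(n),
           p = runif(n, .Machine$double.eps, 1))
}

# Hand-built joint rank table from two score vectors.
make_joint <- function(s1, s2, ids = sprintf("G%04d", seq_along(s1))) {
  d1 <- data.frame(gene_id = ids, score = s1)
  d2 <- data.frame(gene_id = ids, score = s2)
  r1 <- rankenrich::rank_profile(d1)
  r2 <- rankenrich::rank_profile(d2)
  out <- data.frame(gene_id = ids, s1 = s1, s2 = s2,
                    r1 = r1$scaled_rank, r2 = r2$scaled_rank,
                    stringsAsFactors = FALSE)
  class(out) <- c("joint_rank_table", "data.frame")
  out
}

# MANOVA p-value via the base-R reference implementation (Pillai).
manova_oracle_p <- function(joint, members) {
  grp <- factor(joint$gene_id %in% members)
  fit <- stats::manova(cbind(joint$r1, joint$r2) ~ grp)
  summary(fit, test = "Pillai")$stats[1, "Pr(>F)"]
}

null_set_specs <- function() {
  data.frame(set_size = integer(0), n_sets = integer(0),
             delta_glucose = numeric(0), delta_vpa = numeric(0))
}
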