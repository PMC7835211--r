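make_cm <- function(counts, groups) {
  colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("G", seq_len(nrow(counts)))
  count_matrix(counts, data.frame(sample = colnames(counts), group = groups))
}

test_that("filter_low_expression applies the mean-10 rule exactly", {
  # boundary: mean exactly 10 is not "fewer than 10", so retained
  m <- rbind(B10 = c(rep(9, 6), rep(11, 6)), ZERO = rep(0, 12))
  cm <- make_cm(m, rep(c("LG", "HG"), each = 6))
  kept <- filter_low_expression(cm)
  expect_identical(rownames(kept$counts), "B10")

  # toy matrix with means (0, 5, 9.9, 10, 100) -> exactly 2 genes retained
  m2 <- rbind(M1 = rep(0L, 10),
              M2 = rep(5L, 10),
              M3 = c(rep(10L, 9), 9L),   # mean 9.9
              M4 = rep(10L, 10),
              M5 = rep(100L, 10))
  cm2 <- make_cm(m2, rep(c("LG", "HG"), each = 5))
  kept2 <- filter_low_expression(cm2)
  expect_identical(rownames(kept2$counts), c("M4", "M5"))

  # idempotent; order preserved; negative threshold rejected
  expect_identical(filter_low_expression(kept2)$counts, kept2$counts)
  expect_error(filter_low_expression(cm2, -1), ">= 0")
})

test_that("log_cpm matches its closed form and is monotone", {
  m <- matrix(0L, 2, 2, dimnames = list(c("GA", "GB"), c("S1", "S2")))
  m["GB", ] <- c(1e6L - 0L, 1e6L)  # library size 1e6 per sample
  cm <- make_cm(m, c("LG", "HG"))
  le <- log_cpm(cm, pseudo_count = 0.5)
  expect_equal(le$values["GA", "S1"], log2(0.5 / (1e6 + 1) * 1e6),
               tolerance = 1e-12)
  expect_equal(le$values["GA", "S1"], -1.0000014, tolerance = 1e-6)

  set.seed(1)
  base <- matrix(rpois(200, 50), 20, 10)
  cm1 <- make_cm(base, rep(c("LG", "HG"), each = 5))
  v1 <- log_cpm(cm1)$values
  bumped <- base; bumped[3, 1] <- 2 * bumped[3, 1]
  # doubling one count raises its own log-CPM
  expect_gt(log_cpm(make_cm(bumped, rep(c("LG", "HG"), each = 5)))$values[3, 1],
            v1[3, 1])

  # proportional samples with equal library sizes give equal columns
  m3 <- cbind(c(10L, 20L, 70L), c(10L, 20L, 70L))
  rownames(m3) <- paste0("P", 1:3)
  lv <- log_cpm(make_cm(m3, c("LG", "HG")))$values
  expect_equal(lv[, 1], lv[, 2])
})

test_that("bh_adjust matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1), .Machine$double.eps, 1)
    expect_identical(bh_adjust(p), bh_oracle(p))
  }
})

test_that("moderated test handles degenerate and limiting cases", {
  set.seed(2)
  m <- matrix(rpois(60, 100), 6, 10,
              dimnames = list(paste0("G", 1:6), paste0("S", 1:10)))
  cm <- make_cm(m, rep(c("LG", "HG"), each = 5))
  le <- log_cpm(cm)
  le$values[1, ] <- 6.5  # identical expression in every sample: lfc 0, p 1
  de <- moderated_two_group_test(le, "LG", "HG")
  expect_equal(de$log2fc[de$gene_id == "G1"], 0)
  expect_equal(de$p[de$gene_id == "G1"], 1)

  # d0 -> Inf limit: t collapses to lfc / (s0 sqrt(1/na + 1/nb)), normal ref
  s0 <- 0.2
  de_inf <- moderated_two_group_test(le, "LG", "HG",
                                     prior = list(prior_df = Inf, prior_var = s0^2))
  z <- de_inf$log2fc / (s0 * sqrt(1 / 5 + 1 / 5))
  expect_equal(de_inf$p, pmax(2 * pnorm(-abs(z)), .Machine$double.xmin),
               tolerance = 1e-12)

  # zero-variance gene with d0 = 0: flagged, minimum representable p
  m2 <- m; m2[2, 1:5] <- 50L; m2[2, 6:10] <- 200L
  le2 <- log_cpm(make_cm(m2, rep(c("LG", "HG"), each = 5)))
  le2$values[2, 1:5] <- 1; le2$values[2, 6:10] <- 3  # force exact ties
  de0 <- moderated_two_group_test(le2, "LG", "HG",
                                  prior = list(prior_df = 0, prior_var = 1))
  expect_true(attr(de0, "zero_variance")[2])
  expect_equal(de0$p[2], .Machine$double.xmin)

  expect_error(moderated_two_group_test(le, "LG", "NOPE"), ">= 2 samples")
})

test_that("variance-prior fit agrees with the limma oracle", {
  set.seed(11)
  df <- 4
  s2 <- 0.25 * rf(2000, df1 = df, df2 = 8)  # true d0 = 8, s0^2 = 0.25ish
  fit <- estimate_variance_prior(s2, df)
  sq <- limma::squeezeVar(s2, df = df)
  expect_equal(fit$prior_df, sq$df.prior, tolerance = 0.05)
  expect_equal(fit$prior_var, sq$var.prior, tolerance = 0.05)
  # moderated variances follow from the same shrinkage identity
  st <- (fit$prior_df * fit$prior_var + df * s2) / (fit$prior_df + df)
  expect_equal(st, sq$var.post, tolerance = 0.05)
})

test_that("planted log2FC estimates are unbiased within Monte Carlo tolerance", {
  spec <- data.frame(set_size = 50, n_sets = 1, delta_glucose = 2, delta_vpa = 0)
  bias <- vapply(1:5, function(s) {
    sim <- simulate_experiment(sim_config(n_genes = 5000, seed = s,
                                          set_specs = spec))
    le <- log_cpm(filter_low_expression(sim$counts))
    de <- moderated_two_group_test(le, "LG", "HG")
    members <- intersect(sim$sets[[1]], de$gene_id)
    mean(de$log2fc[match(members, de$gene_id)]) - 2
  }, 0)
  expect_lt(abs(mean(bias)), 0.15)
})
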