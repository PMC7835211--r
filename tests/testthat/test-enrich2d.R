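test_that("join_contrasts places identical and negated contrasts on diagonals", {
  de <- random_de_table(40, seed = 2)
  j_same <- join_contrasts(de, de)
  expect_equal(j_same$r1, j_same$r2)
  expect_equal(sum(j_same$r1), 0)
  expect_equal(sum(j_same$r2), 0)

  neg <- de_table(de$gene_id, -de$log2fc, de$p)
  j_neg <- join_contrasts(de, neg)
  expect_equal(j_neg$r1, -j_neg$r2)

  other <- de_table(paste0("X", de$gene_id), de$log2fc, de$p)
  expect_error(join_contrasts(de, other), ">= 10")
})

test_that("joining is symmetric and restricted to the common universe", {
  de1 <- random_de_table(60, seed = 3)
  de2 <- random_de_table(45, seed = 4)  # shares first 45 genes
  j <- join_contrasts(de1, de2)
  expect_equal(nrow(j), 45)
  js <- join_contrasts(de2, de1)
  i <- match(j$gene_id, js$gene_id)
  expect_equal(js$r1[i], j$r2)
  expect_equal(js$r2[i], j$r1)
})

test_that("duplicate gene rows are resolved by smallest p at join time", {
  raw <- data.frame(gene_id = c("A", "A", "B", rep(sprintf("C%02d", 1:10), 1)),
                    log2fc = c(1, 5, -1, rnorm(10)),
                    p = c(0.5, 0.001, 0.2, runif(10, 0.01, 1)))
  de2 <- de_table(unique(raw$gene_id), rnorm(12), runif(12, 0.01, 1))
  expect_message(j <- join_contrasts(raw, de2), "keeping smallest p")
  expect_equal(j$s1[j$gene_id == "A"],
               sign(5) * -log10(0.001))
})

test_that("set_scores_2d matches the closed form for a top flank", {
  # members occupy the top 2 ranks of dimension 1 with N = 10
  j <- make_joint(s1 = 10:1, s2 = rnorm(10))
  top2 <- j$gene_id[order(-j$s1)][1:2]
  sc <- set_scores_2d(j, top2)
  expect_equal(sc$s1, (10 - 2) / 10)
  expect_equal(sc$s_dist, sqrt(sc$s1^2 + sc$s2^2))
  expect_message(expect_null(set_scores_2d(j, j$gene_id[1])), "skipped")
})

test_that("symmetric membership gives null scores and p = 1", {
  # members hold rank pairs summing to N+1 in both dimensions, so their mean
  # rank vector equals the grand mean; dimension 2 is scrambled elsewhere to
  # keep the pooled covariance non-singular
  q <- c(1, 7, 3, 11, 16, 2, 14, 4, 9, 12, 8, 13, 6, 18, 10, 5, 17, 15, 19, 20)
  j <- make_joint(s1 = 1:20, s2 = q)
  members <- j$gene_id[c(1, 20, 5, 16)]  # dim-2 ranks 1, 20, 16, 5
  sc <- set_scores_2d(j, members)
  expect_equal(sc$s1, 0)
  expect_equal(sc$s2, 0)
  mv <- manova_rank_test(j, members)
  expect_equal(mv$T2, 0)
  expect_equal(mv$p, 1)
})

test_that("manova_rank_test matches the base-R MANOVA oracle", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(25:60, 1)
    j <- make_joint(s1 = rnorm(n), s2 = rnorm(n))
    members <- sample(j$gene_id, sample(4:10, 1))
    got <- manova_rank_test(j, members)
    expect_equal(got$p, manova_oracle_p(j, members), tolerance = 1e-10)
  }
})

test_that("manova is invariant to order-preserving score transforms", {
  set.seed(8)
  s1 <- rnorm(50); s2 <- rnorm(50)
  j1 <- make_joint(s1, s2)
  j2 <- make_joint(exp(s1), 3 * s2 - 1)  # same orderings
  members <- j1$gene_id[sample(50, 8)]
  expect_equal(manova_rank_test(j1, members)$p,
               manova_rank_test(j2, members)$p)
})

test_that("degenerate rank dimensions are reported", {
  j <- make_joint(s1 = 1:12, s2 = rep(1, 12))  # dimension 2 all tied -> constant
  expect_error(manova_rank_test(j, j$gene_id[1:4]), "dimension 2")
  j3 <- make_joint(s1 = 1:12, s2 = rnorm(12))
  expect_error(manova_rank_test(j3, j3$gene_id[1]), "at least 2")
  expect_error(manova_rank_test(j3, j3$gene_id[1:11]), "3 non-members")
})

test_that("enrich2d_all adjusts with BH over exactly the tested sets", {
  set.seed(10)
  j <- make_joint(s1 = rnorm(80), s2 = rnorm(80))
  sets <- gene_set_collection(list(
    A = sample(j$gene_id, 15), B = sample(j$gene_id, 20),
    C = sample(j$gene_id, 12), SMALL = sample(j$gene_id, 3)))
  expect_message(res <- enrich2d_all(j, sets, min_size = 10), "SMALL")
  expect_identical(sort(res$set_name), c("A", "B", "C"))
  expect_equal(res$fdr, bh_adjust(res$p))
  expect_true(!is.unsorted(res$p))

  one <- suppressMessages(enrich2d_all(j, gene_set_collection(
    list(A = sets$A)), min_size = 10))
  expect_equal(one$fdr, one$p)  # BH with m = 1
})

test_that("swapping contrasts swaps (s1, s2) and preserves p", {
  de1 <- random_de_table(60, seed = 13)
  de2 <- random_de_table(60, seed = 14)
  sets <- gene_set_collection(list(S = de1$gene_id[sample(60, 12)]))
  r12 <- suppressMessages(enrich2d_all(join_contrasts(de1, de2), sets))
  r21 <- suppressMessages(enrich2d_all(join_contrasts(de2, de1), sets))
  expect_equal(r12$s1, r21$s2)
  expect_equal(r12$s2, r21$s1)
  expect_equal(r12$p, r21$p)
})

test_that("density_grid conserves genes and respects geometry", {
  de <- random_de_table(200, seed = 15)
  j <- join_contrasts(de, random_de_table(200, seed = 16))
  expect_equal(sum(density_grid(j, 1)), nrow(j))   # single cell holds all
  for (b in c(2, 7, 50)) expect_equal(sum(density_grid(j, b)), nrow(j))

  j_diag <- join_contrasts(de, de)
  g2 <- density_grid(j_diag, 2)
  expect_equal(g2[1, 2], 0L)
  expect_equal(g2[2, 1], 0L)

  # swapping the inputs transposes the grid
  j_a <- join_contrasts(de, random_de_table(200, seed = 16))
  j_b <- join_contrasts(random_de_table(200, seed = 16), de)
  expect_equal(unname(density_grid(j_b, 5)), unname(t(density_grid(j_a, 5))))
  expect_error(density_grid(j, 0), ">= 1")
})

test_that("uniform independent ranks fill a 10x10 grid evenly", {
  set.seed(20)
  n <- 5000
  j <- make_joint(s1 = rnorm(n), s2 = rnorm(n))
  g <- density_grid(j, 10)
  expect_equal(sum(g), n)
  # multinomial cell sd ~ sqrt(n p (1-p)) ~ 7; allow 5 sigma
  expect_true(all(abs(g - n / 100) < 5 * sqrt(n * 0.01 * 0.99)))
})
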