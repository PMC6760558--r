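test_that("mann_whitney matches exact enumeration in the small untied case", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u_stat, 0)
  expect_equal(res$p, 0.1) # 2/20 assignments as extreme

  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1))
    y <- rnorm(sample(2:6, 1))
    res <- mann_whitney(x, y)
    oracle <- enum_mw(x, y)
    expect_equal(res$u_stat, oracle$u)
    expect_equal(res$p, oracle$p, tolerance = 1e-12)
  }
})

test_that("mann_whitney is symmetric under identical inputs and rejects bad ones", {
  x <- c(1, 2, 2, 5, 7)
  expect_equal(mann_whitney(x, x)$p, 1, tolerance = 0.05)
  expect_equal(mann_whitney(x, x)$u_stat, length(x)^2 / 2)
  expect_error(mann_whitney(numeric(0), x), "2 observations")
  expect_error(mann_whitney(c(1, NA), x), "finite")
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  # q >= p elementwise, and permutation invariance
  set.seed(4)
  p <- runif(50)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("run_de applies the dual q / fold-change criterion per platform", {
  # strong-but-small shift: q clears 0.05, |log2FC| ~ 0.3 below the
  # RNA-seq cut-off of 0.585, so the gene must stay ns on rnaseq but
  # count as differential on the permissive microarray scale (0.05)
  fx <- two_group_expr(
    n_genes = 40, n1 = 60, n2 = 60, n_shift = 3,
    delta = 0.3, sd = 0.3, seed = 8
  )
  de_rna <- suppressMessages(run_de(fx$expr, fx$annot))
  hit <- de_rna[de_rna$gene_id %in% fx$shifted, ]
  expect_true(all(hit$q < 0.05))
  expect_true(all(abs(hit$log2fc) < 0.585))
  expect_true(all(hit$direction == "ns"))

  fx$expr$platform <- "microarray"
  de_arr <- suppressMessages(run_de(fx$expr, fx$annot))
  expect_true(all(de_arr$direction[de_arr$gene_id %in% fx$shifted] == "up_in_ets_pos"))

  expect_error(
    suppressMessages(run_de(fx$expr, fx$annot[fx$annot$ets_status == "ets_pos", ])),
    "per ETS stratum"
  )
})

test_that("relabeling the strata flips fold-change signs and directions", {
  fx <- two_group_expr(n_shift = 5, delta = 2, seed = 15)
  de1 <- suppressMessages(run_de(fx$expr, fx$annot))
  swapped <- fx$annot
  swapped$ets_status <- ifelse(swapped$ets_status == "ets_pos", "ets_neg", "ets_pos")
  swapped$subtype <- ifelse(swapped$ets_status == "ets_pos", "ERG", "SPOP")
  de2 <- suppressMessages(run_de(fx$expr, swapped))
  expect_equal(de2$log2fc, -de1$log2fc)
  expect_equal(de2$p, de1$p)
  flip <- c(up_in_ets_pos = "up_in_ets_neg", up_in_ets_neg = "up_in_ets_pos", ns = "ns")
  expect_identical(de2$direction, unname(flip[de1$direction]))
})

test_that("cohort intersection keeps concordant genes and is symmetric", {
  fx <- two_group_expr(n1 = 15, n2 = 15, n_shift = 5, delta = 3, seed = 23)
  de <- suppressMessages(run_de(fx$expr, fx$annot))
  self <- intersect_cohorts(de, de)
  expect_setequal(self$overlap_genes, de$gene_id[de$direction != "ns"])
  expect_equal(self$fc_correlation, 1)
  expect_identical(self$n_up_ets_pos + self$n_up_ets_neg, self$n_overlap)

  # discordant gene is excluded
  de_b <- de
  i <- match(fx$shifted[1], de_b$gene_id)
  de_b$direction[i] <- "up_in_ets_neg"
  de_b$log2fc[i] <- -de_b$log2fc[i]
  inter <- intersect_cohorts(de, de_b)
  expect_false(fx$shifted[1] %in% inter$overlap_genes)

  ba <- intersect_cohorts(de_b, de)
  expect_setequal(ba$overlap_genes, inter$overlap_genes)
  expect_identical(ba$n_overlap, inter$n_overlap)

  no_share <- de_b
  no_share$gene_id <- paste0("other_", no_share$gene_id)
  expect_error(intersect_cohorts(de, no_share), "share no gene")
})

test_that("two-platform synthetic cohorts intersect to the planted genes", {
  sim <- small_sim(
    seed = 41, n_per_category = 10,
    n_tumor_ets_pos = 60, n_tumor_ets_neg = 60
  )
  de_a <- suppressMessages(run_de(sim$expr$rnaseq, sim$annotation))
  de_b <- suppressMessages(run_de(sim$expr$microarray, sim$annotation))
  conc <- intersect_cohorts(de_a, de_b)
  planted <- sim$truth$gene_id[sim$truth$category != "null"]
  nulls <- sim$truth$gene_id[sim$truth$category == "null"]
  expect_gte(mean(planted %in% conc$overlap_genes), 0.90)
  expect_lte(mean(nulls %in% conc$overlap_genes), 0.05)
  expect_gt(conc$fc_correlation, 0.8)
})
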