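dir_tab <- function(ids, dirs) {
  data.frame(gene_id = ids, direction = dirs, stringsAsFactors = FALSE)
}

test_that("the category map covers every direction pattern exactly once", {
  pats <- expand.grid(
    dn = c("up", "dn", "ns"), dp = c("up", "dn", "ns"),
    stringsAsFactors = FALSE
  )
  ids <- sprintf("g%d", seq_len(nrow(pats)))
  res <- assign_categories(ids, dir_tab(ids, pats$dn), dir_tab(ids, pats$dp))
  got <- setNames(res$category, paste(pats$dn, pats$dp, sep = ","))
  expect_identical(got[["up,ns"]], "ets_neg_up")
  expect_identical(got[["dn,ns"]], "ets_neg_dn")
  expect_identical(got[["ns,up"]], "ets_pos_up")
  expect_identical(got[["ns,dn"]], "ets_pos_dn")
  expect_identical(got[["up,up"]], "both_up")
  expect_identical(got[["ns,ns"]], "removed")
  for (other in c("dn,dn", "up,dn", "dn,up")) {
    expect_identical(got[[other]], "other_pattern")
  }
  # partition: one category per target gene, counts sum to target count
  expect_identical(nrow(res), length(ids))
  expect_identical(sum(table(res$category)), length(ids))
})

test_that("non-targets are excluded and unknown genes are errors", {
  targets <- data.frame(gene_id = c("a", "b"), is_target = c(TRUE, FALSE))
  dn <- dir_tab(c("a", "b"), c("up", "up"))
  dp <- dir_tab(c("a", "b"), c("ns", "ns"))
  res <- assign_categories(targets, dn, dp)
  expect_identical(res$gene_id, "a")

  expect_error(
    assign_categories(targets, dir_tab(c("a", "zzz"), c("up", "up")), dp),
    "zzz"
  )
  expect_error(
    assign_categories(c("a", "b"), dn[1, ], dp),
    "lacks a direction"
  )
})

test_that("tumor-vs-normal directions recover planted category structure", {
  sim <- small_sim(seed = 61, n_normal = 20)
  tg <- sim$truth$gene_id[sim$truth$is_ar_target]
  dn <- tumor_vs_normal(sim$expr$rnaseq, sim$annotation, "ets_neg", genes = tg)
  dp <- tumor_vs_normal(sim$expr$rnaseq, sim$annotation, "ets_pos", genes = tg)
  cat_of <- setNames(sim$truth$category, sim$truth$gene_id)
  neg_up <- tg[cat_of[tg] == "ets_neg_up"]
  expect_true(all(dn$direction[match(neg_up, dn$gene_id)] == "up"))
  expect_gte(mean(dp$direction[match(neg_up, dp$gene_id)] == "ns"), 0.8)
  pos_dn <- tg[cat_of[tg] == "ets_pos_dn"]
  expect_true(all(dp$direction[match(pos_dn, dp$gene_id)] == "dn"))

  expect_error(
    tumor_vs_normal(
      sim$expr$rnaseq,
      sim$annotation[sim$annotation$tissue == "tumor", ], "ets_neg"
    ),
    "adjacent_normal"
  )
})

test_that("duplicating normals as tumors yields no tumor-vs-normal calls", {
  set.seed(71)
  n <- 24
  vals <- matrix(rnorm(60 * n, 5), 60, n,
    dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:n))
  )
  em <- expr_matrix(vals, "rnaseq")
  ann <- data.frame(
    sample_id = sprintf("s%02d", 1:n), cohort = "c",
    tissue = rep(c("tumor", "adjacent_normal"), each = n / 2),
    ets_status = rep(c("ets_neg", "unknown"), each = n / 2),
    subtype = rep(c("SPOP", "none"), each = n / 2)
  )
  # tumors are literal copies of the normals
  em$values[, 1:(n / 2)] <- em$values[, (n / 2 + 1):n]
  tvn <- tumor_vs_normal(em, ann, "ets_neg")
  expect_true(all(tvn$direction == "ns"))
})

test_that("normal-median normalization centers normals at zero", {
  ann <- data.frame(
    sample_id = c("t1", "t2", "n1"), cohort = "c",
    tissue = c("tumor", "tumor", "adjacent_normal"),
    ets_status = c("ets_pos", "ets_neg", "unknown"),
    subtype = c("ERG", "SPOP", "none")
  )
  zeros <- tiny_expr(rep(0, 6), c("a", "b"), c("t1", "t2", "n1"))
  expect_equal(normal_median_normalize(zeros, ann)$values, zeros$values)

  em <- tiny_expr(c(5, 7, 3, 1, 2, 10), c("a", "b"), c("t1", "t2", "n1"))
  norm <- normal_median_normalize(em, ann)
  # single normal: tumor value minus that normal's value
  expect_equal(norm$values["a", ], c(t1 = 2, t2 = 4, n1 = 0))
  expect_equal(norm$values["b", ], c(t1 = -9, t2 = -8, n1 = 0))

  set.seed(5)
  ann5 <- data.frame(
    sample_id = sprintf("s%d", 1:7), cohort = "c",
    tissue = rep(c("tumor", "adjacent_normal"), c(2, 5)),
    ets_status = rep(c("ets_pos", "unknown"), c(2, 5)),
    subtype = rep(c("ERG", "none"), c(2, 5))
  )
  em5 <- expr_matrix(
    matrix(rnorm(70), 10, 7,
      dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:7))
    ),
    "rnaseq"
  )
  norm5 <- normal_median_normalize(em5, ann5)
  med <- apply(norm5$values[, 3:7], 1, median)
  expect_equal(unname(med), rep(0, 10))

  expect_error(
    normal_median_normalize(em5, ann5[ann5$tissue == "tumor", ]),
    "no adjacent_normal"
  )
})
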