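test_that("simulation is bitwise reproducible and validates its config", {
  a <- small_sim(seed = 21)
  b <- small_sim(seed = 21)
  expect_identical(a$expr$rnaseq$values, b$expr$rnaseq$values)
  expect_identical(a$expr$microarray$values, b$expr$microarray$values)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$sites, b$sites)
  expect_identical(a$survival, b$survival)
  expect_identical(a$truth, b$truth)

  c <- small_sim(seed = 22)
  expect_false(identical(a$expr$rnaseq$values, c$expr$rnaseq$values))

  expect_error(
    simulation_config(n_genes = 20, n_per_category = 10),
    "planted"
  )
  expect_error(simulation_config(n_normal = 1), ">= 2")
  expect_error(simulation_config(frac_ar_bound = 1.2), "frac_ar_bound")
})

test_that("planted structure matches the configured counts and categories", {
  sim <- small_sim(seed = 5, n_per_category = 8, n_extra_both_up = 1)
  tab <- table(sim$truth$category)
  for (cat in c("ets_neg_up", "ets_neg_dn", "ets_pos_up", "ets_pos_dn")) {
    expect_identical(unname(tab[[cat]]), 8L)
  }
  expect_identical(unname(tab[["both_up"]]), 9L)
  # every planted gene is AR-bound
  planted <- sim$truth$category != "null"
  expect_true(all(sim$truth$is_ar_target[planted]))
  # annotation invariants: tumors labeled, subtype consistent
  expect_silent(validate_annotation(sim$annotation))
  tum <- sim$annotation$tissue == "tumor"
  expect_true(all(sim$annotation$ets_status[tum] != "unknown"))
})

test_that("binding-site geometry honors the 25 kb construction by direct check", {
  sim <- small_sim(seed = 9)
  gm <- sim$gene_models
  dist_to_tss <- function(tss) {
    d <- ifelse(sim$sites$start > tss, sim$sites$start - tss,
      ifelse(sim$sites$end <= tss, tss - sim$sites$end, 0L)
    )
    min(d)
  }
  min_d <- vapply(gm$tss, dist_to_tss, numeric(1))
  bound <- sim$truth$is_ar_target[match(gm$gene_id, sim$truth$gene_id)]
  expect_true(all(min_d[bound] <= 25000))
  expect_true(all(min_d[!bound] >= 50000))
})

test_that("with zero effect size no gene is called differential beyond the FDR", {
  # lighter replicate of the null-calibration property (the dedicated
  # acceptance check runs 20 replicates at full size)
  fracs <- vapply(1:4, function(s) {
    sim <- simulate_cohort(simulation_config(
      n_tumor_ets_pos = 20, n_tumor_ets_neg = 20, n_normal = 2,
      n_genes = 400, n_per_category = 0, n_extra_both_up = 0,
      effect_size = 0, seed = 100 + s
    ))
    de <- suppressMessages(run_de(sim$expr$rnaseq, sim$annotation))
    mean(de$direction != "ns")
  }, numeric(1))
  expect_lt(mean(fracs), 0.05)
})

test_that("planted DE direction is recovered at moderate effect and depth", {
  hits <- unlist(lapply(1:4, function(s) {
    sim <- simulate_cohort(simulation_config(
      n_tumor_ets_pos = 50, n_tumor_ets_neg = 50, n_normal = 5,
      n_genes = 300, n_per_category = 13, n_extra_both_up = 0,
      effect_size = 1.0, seed = 200 + s
    ))
    de <- suppressMessages(run_de(sim$expr$rnaseq, sim$annotation))
    truth <- sim$truth
    expected <- c(
      ets_neg_up = "up_in_ets_neg", ets_neg_dn = "up_in_ets_pos",
      ets_pos_up = "up_in_ets_pos", ets_pos_dn = "up_in_ets_neg",
      both_up = "up_in_ets_pos"
    )
    planted <- truth$category != "null"
    de$direction[match(truth$gene_id[planted], de$gene_id)] ==
      expected[truth$category[planted]]
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("decoy planting flags AR-bound null genes and leaves data untouched", {
  sim <- small_sim(seed = 13)
  n_avail <- sum(sim$truth$is_ar_target & sim$truth$category == "null")
  expect_gt(n_avail, 5)

  same <- plant_decoys(sim, 0)
  expect_identical(same$truth, sim$truth)

  with_dec <- plant_decoys(sim, 5)
  expect_identical(sum(with_dec$truth$is_decoy), 5L)
  expect_true(all(with_dec$truth$is_ar_target[with_dec$truth$is_decoy]))
  expect_true(all(with_dec$truth$category[with_dec$truth$is_decoy] == "null"))
  expect_identical(with_dec$expr$rnaseq$values, sim$expr$rnaseq$values)

  expect_error(plant_decoys(sim, n_avail + 1), "available")
})

test_that("decoy tumor-vs-normal p-values are uniform on (0,1)", {
  ps <- unlist(lapply(1:3, function(s) {
    sim <- small_sim(seed = 300 + s, n_normal = 20)
    sim <- plant_decoys(sim, 10)
    dec <- sim$truth$gene_id[sim$truth$is_decoy]
    tvn <- tumor_vs_normal(sim$expr$rnaseq, sim$annotation, "pooled", genes = dec)
    tvn$p
  }))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated artifacts write to disk in their standard formats", {
  sim <- small_sim(seed = 2)
  dir <- withr::local_tempdir()
  write_cohort_sim(sim, dir)
  back <- read_expression(file.path(dir, "expr_rnaseq.tsv"), "rnaseq")
  expect_lt(max(abs(back$values - sim$expr$rnaseq$values)), 1e-9)
  expect_identical(nrow(read_bed(file.path(dir, "ar_sites.bed"))), nrow(sim$sites))
  expect_identical(read_annotation(file.path(dir, "annotation.tsv")), sim$annotation)
  expect_identical(
    read_survival(file.path(dir, "survival.tsv"))$sample_id,
    sim$survival$sample_id
  )
})
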