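test_that("expression TSV round-trips ids exactly and values to 1e-12", {
  em <- tiny_expr(c(1.25, -3.5, 0.125, 7, 2.5, -1), c("KLK3", "ERG"),
    c("s1", "s2", "s3"),
    platform = "rnaseq"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(em, path)
  back <- read_expression(path, "rnaseq")
  expect_identical(gene_ids(back), gene_ids(em))
  expect_identical(sample_ids(back), sample_ids(em))
  expect_lt(max(abs(back$values - em$values)), 1e-12)
  expect_identical(back$platform, "rnaseq")

  set.seed(3)
  big <- expr_matrix(
    matrix(rnorm(200), 20, 10,
      dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10))
    ),
    "microarray"
  )
  write_expression(big, path)
  back <- read_expression(path, "microarray")
  expect_identical(gene_ids(back), gene_ids(big))
  expect_lt(max(abs(back$values - big$values)), 1e-12)
})

test_that("expression reader rejects duplicates and non-numeric cells by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\ts1\ts2",
    "ERG\t1\t2",
    "ERG\t3\t4"
  ), path)
  expect_error(read_expression(path), "ERG")

  writeLines(c(
    "gene_id\ts1\ts2",
    "KLK3\t1\t2",
    "ERG\t3\tNA"
  ), path)
  expect_error(read_expression(path), "ERG.*s2")

  # constructor-level invariants
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s", "s")))
  expect_error(expr_matrix(m, "rnaseq"), "duplicate sample")
})

test_that("BED parsing preserves 0-based half-open coordinates and flags bad lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr2\t0\t50\textra\tcols"), path)
  sites <- read_bed(path, source = "studyA")
  expect_identical(sites$chrom, c("chr1", "chr2"))
  expect_identical(sites$start, c(100L, 0L))
  expect_identical(sites$end, c(200L, 50L))
  expect_identical(sites$source, c("studyA", "studyA"))

  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), path)
  expect_error(read_bed(path), "line 2")

  # exact coordinate round-trip through write_bed
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(sites, out)
  back <- read_bed(out, source = "studyA")
  expect_identical(back[c("chrom", "start", "end")], sites[c("chrom", "start", "end")])
})

test_that("binding sites pooled from several files concatenate with their labels", {
  paths <- vapply(1:3, function(i) tempfile(fileext = ".bed"), "")
  ns <- c(2L, 3L, 1L)
  for (i in 1:3) {
    writeLines(sprintf("chr1\t%d\t%d", (1:ns[i]) * 100, (1:ns[i]) * 100 + 50), paths[i])
  }
  pooled <- do.call(rbind, Map(read_bed, paths, source = c("a", "b", "c")))
  expect_identical(nrow(pooled), sum(ns))
  expect_identical(as.vector(table(pooled$source)[c("a", "b", "c")]), ns)
})

test_that("GMT parsing discards descriptions, dedups members, and sizes sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "S1\tna\tA\tB\tC",
    paste(c("HALLMARK_LIKE", "desc", sprintf("G%03d", 1:101)), collapse = "\t")
  ), path)
  gs <- read_gmt(path)
  expect_identical(gs$sets$S1, c("A", "B", "C"))
  expect_identical(length(gs$sets$HALLMARK_LIKE), 101L)

  writeLines("S2\tna\tA\tA", path)
  expect_warning(gs <- read_gmt(path), "duplicate")
  expect_identical(gs$sets$S2, "A")

  writeLines(c("S1\tna\tA", "S3\tonlydesc"), path)
  expect_error(read_gmt(path), "line 2")

  # round trip
  gs <- gene_set_collection("coll", list(S1 = c("A", "B"), S2 = c("C")))
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, out)
  expect_identical(read_gmt(out)$sets, gs$sets)
})

test_that("annotation, gene model and survival tables validate their invariants", {
  ann <- data.frame(
    sample_id = c("t1", "n1"), cohort = "c", tissue = c("tumor", "adjacent_normal"),
    ets_status = c("ets_pos", "unknown"), subtype = c("ERG", "none")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, path)
  expect_identical(read_annotation(path), ann)

  bad <- ann
  bad$ets_status[1] <- "ets_neg" # contradicts ERG subtype
  expect_error(validate_annotation(bad), "inconsistent")

  gm <- data.frame(gene_id = c("a", "b"), chrom = "chr1", tss = c(0L, 100L), strand = c("+", "-"))
  write_gene_models(gm, path)
  expect_identical(read_gene_models(path), gm)
  gm$strand[2] <- "*"
  expect_error(validate_gene_models(gm), "strand")

  sv <- data.frame(sample_id = c("t1", "t2"), time_months = c(10.5, 24), event = c(1L, 0L))
  write_survival(sv, path)
  back <- read_survival(path)
  expect_identical(back$event, c(TRUE, FALSE))
  expect_equal(back$time_months, sv$time_months)
  sv$time_months[1] <- 0
  expect_error(validate_survival(sv), "positive")
})
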