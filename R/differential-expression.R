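#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()] exposing the U statistic
#' and two-sided p-value used throughout the differential-expression
#' stages. An exact p-value is computed when the pooled sample size is
#' at most 12 and there are no ties; otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A list with `u_stat` (the U statistic for `x`) and `p`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group needs at least 2 observations")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("values must be finite")
  no_ties <- !anyDuplicated(c(x, y))
  exact <- (length(x) + length(y)) <= 12L && no_ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(u_stat = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#' Delegates to [stats::p.adjust()] after validating the inputs.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || !length(p)) abort("`p` must be a non-empty numeric vector")
  if (any(!is.finite(p) | p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression thresholds
#'
#' The dual significance criterion used throughout: BH q below `q_max`
#' AND absolute log2 fold change above `fc_min`. The fold-change default
#' is platform dependent — 0.585 on the RNA-seq scale and 0.05 on the
#' compressed microarray (SCAN-style) scale.
#'
#' @param q_max FDR threshold, in (0, 1).
#' @param fc_min Minimum absolute log2 fold change (>= 0); `NULL` picks
#'   the platform default at run time.
#' @return An object of class `de_config`.
#' @export
de_config <- function(q_max = 0.05, fc_min = NULL) {
  if (!is_number(q_max) || q_max <= 0 || q_max >= 1) abort("`q_max` must lie in (0, 1)")
  if (!is.null(fc_min) && (!is_number(fc_min) || fc_min < 0)) {
    abort("`fc_min` must be >= 0")
  }
  structure(list(q_max = q_max, fc_min = fc_min), class = "de_config")
}

.default_fc_min <- c(rnaseq = 0.585, microarray = 0.05)

resolve_fc_min <- function(config, platform) {
  if (!is.null(config$fc_min)) config$fc_min else .default_fc_min[[platform]]
}

# Per-gene two-group comparison shared by the ETS+/ETS- and the
# tumor-vs-normal stages. log2fc is mean(group1) - mean(group2).
de_table <- function(values, idx1, idx2, q_max, fc_min) {
  res <- apply(values, 1L, function(v) {
    mw <- mann_whitney(v[idx1], v[idx2])
    c(mw$u_stat, mw$p)
  })
  u_stat <- res[1L, ]
  p <- res[2L, ]
  p[!is.finite(p)] <- 1 # fully tied (e.g. constant) genes carry no evidence
  q <- bh_fdr(p)
  log2fc <- rowMeans(values[, idx1, drop = FALSE]) -
    rowMeans(values[, idx2, drop = FALSE])
  sig <- q < q_max & abs(log2fc) > fc_min
  data.frame(
    gene_id = rownames(values), u_stat = u_stat, p = p, q = q,
    log2fc = unname(log2fc), significant = sig,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-gene ETS+ versus ETS- differential expression
#'
#' Tests every gene between ETS-positive and ETS-negative tumors with a
#' two-sided Mann-Whitney U test, adjusts with Benjamini-Hochberg, and
#' calls a direction only for genes passing the dual criterion
#' (q < `q_max` and |log2 FC| > `fc_min`). Fold change is the difference
#' of group means on the log2 scale, ETS+ minus ETS-.
#'
#' @param expr An [expr_matrix()].
#' @param annotation Annotation `data.frame`; only its tumor samples
#'   with known ETS status that appear in `expr` are used.
#' @param config A [de_config()]; a `NULL` `fc_min` resolves to the
#'   platform default of `expr`.
#' @return A `data.frame` of class `de_result` with columns `gene_id`,
#'   `u_stat`, `p`, `q`, `log2fc` and `direction`
#'   (`up_in_ets_pos` / `up_in_ets_neg` / `ns`).
#' @export
run_de <- function(expr, annotation, config = de_config()) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(config, "de_config"))
  validate_annotation(annotation)
  tum <- annotation[annotation$tissue == "tumor" &
    annotation$ets_status != "unknown" &
    annotation$sample_id %in% sample_ids(expr), ]
  pos <- tum$sample_id[tum$ets_status == "ets_pos"]
  neg <- tum$sample_id[tum$ets_status == "ets_neg"]
  if (length(pos) < 2L || length(neg) < 2L) {
    abort(
      "need >= 2 tumor samples per ETS stratum (got ", length(pos),
      " ets_pos, ", length(neg), " ets_neg)"
    )
  }
  fc_min <- resolve_fc_min(config, expr$platform)
  tab <- de_table(
    expr$values,
    match(pos, sample_ids(expr)), match(neg, sample_ids(expr)),
    config$q_max, fc_min
  )
  tab$direction <- ifelse(!tab$significant, "ns",
    ifelse(tab$log2fc > 0, "up_in_ets_pos", "up_in_ets_neg")
  )
  tab$significant <- NULL
  n_sig <- sum(tab$direction != "ns")
  message(sprintf(
    "run_de [%s]: %d of %d genes differential (%.1f%%) at q<%g, |log2FC|>%g",
    expr$platform, n_sig, nrow(tab), 100 * n_sig / nrow(tab),
    config$q_max, fc_min
  ))
  class(tab) <- c("de_result", "data.frame")
  tab
}

#' Concordant cross-cohort intersection of differential genes
#'
#' The overlap is the set of genes called differential in both cohorts
#' with the same direction; discordant genes are excluded. The Pearson
#' correlation of log2 fold changes over the overlap quantifies
#' cross-platform agreement.
#'
#' @param de_a,de_b `de_result` tables from two cohorts sharing a gene
#'   id space.
#' @return A list of class `cohort_concordance` with `overlap_genes`,
#'   `n_overlap`, `n_up_ets_pos`, `n_up_ets_neg` and `fc_correlation`.
#' @export
intersect_cohorts <- function(de_a, de_b) {
  shared <- intersect(de_a$gene_id, de_b$gene_id)
  if (!length(shared)) abort("the two cohorts share no gene ids")
  a <- de_a[match(shared, de_a$gene_id), ]
  b <- de_b[match(shared, de_b$gene_id), ]
  concordant <- a$direction != "ns" & a$direction == b$direction
  overlap <- shared[concordant]
  fc_cor <- if (length(overlap) >= 3L) {
    stats::cor(a$log2fc[concordant], b$log2fc[concordant])
  } else {
    NA_real_
  }
  structure(
    list(
      overlap_genes = overlap,
      n_overlap = length(overlap),
      n_up_ets_pos = sum(a$direction[concordant] == "up_in_ets_pos"),
      n_up_ets_neg = sum(a$direction[concordant] == "up_in_ets_neg"),
      fc_correlation = fc_cor
    ),
    class = "cohort_concordance"
  )
}

#' @export
print.cohort_concordance <- function(x, ...) {
  cat("<cohort_concordance> ", x$n_overlap, " concordant genes (",
    x$n_up_ets_pos, " up in ETS+, ", x$n_up_ets_neg,
    " up in ETS-); log2FC r = ", round(x$fc_correlation, 3), "\n",
    sep = ""
  )
  invisible(x)
}
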