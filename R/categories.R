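#' Per-gene tumor-versus-normal direction within an ETS stratum
#'
#' The subtractive stage compares each tumor stratum against the
#' adjacent-normal samples of the same cohort with the same machinery
#' as the ETS+/ETS- comparison: two-sided Mann-Whitney U per gene,
#' Benjamini-Hochberg adjustment across the tested genes, and the dual
#' q / fold-change criterion. Fold change is tumor minus normal on the
#' log2 scale.
#'
#' @param expr An [expr_matrix()].
#' @param annotation Annotation `data.frame` covering the matrix's
#'   samples.
#' @param stratum `"ets_pos"`, `"ets_neg"`, or `"pooled"` (all tumors
#'   with known ETS status, the alternative removal criterion).
#' @param config A [de_config()]; `fc_min = NULL` resolves to the
#'   platform default.
#' @param genes Optional gene ids to restrict the test (and the BH
#'   adjustment) to, e.g. the AR-target list of the subtractive stage.
#' @return A `data.frame` with columns `gene_id`, `u_stat`, `p`, `q`,
#'   `log2fc` and `direction` (`up` / `dn` / `ns`).
#' @export
tumor_vs_normal <- function(expr, annotation,
                            stratum = c("ets_neg", "ets_pos", "pooled"),
                            config = de_config(), genes = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(config, "de_config"))
  stratum <- match.arg(stratum)
  validate_annotation(annotation)
  ann <- annotation[annotation$sample_id %in% sample_ids(expr), ]
  tum <- ann$sample_id[ann$tissue == "tumor" &
    if (stratum == "pooled") ann$ets_status != "unknown" else ann$ets_status == stratum]
  nrm <- ann$sample_id[ann$tissue == "adjacent_normal"]
  if (length(nrm) < 2L) abort("need >= 2 adjacent_normal samples")
  if (length(tum) < 2L) abort("need >= 2 tumor samples in stratum '", stratum, "'")
  if (!is.null(genes)) expr <- subset_expr(expr, genes = genes)
  fc_min <- resolve_fc_min(config, expr$platform)
  tab <- de_table(
    expr$values,
    match(tum, sample_ids(expr)), match(nrm, sample_ids(expr)),
    config$q_max, fc_min
  )
  tab$direction <- ifelse(!tab$significant, "ns", ifelse(tab$log2fc > 0, "up", "dn"))
  tab$significant <- NULL
  tab
}

.category_levels <- c(
  "ets_neg_up", "ets_neg_dn", "ets_pos_up", "ets_pos_dn",
  "both_up", "removed", "other_pattern"
)

#' Assign AR-target genes to the five ETS-dependent categories
#'
#' The subtractive-genomics classification: each AR-target gene's
#' tumor-versus-normal direction in the ETS- stratum and in the ETS+
#' stratum determines its category —
#' (up, ns) `ets_neg_up`; (dn, ns) `ets_neg_dn`; (ns, up) `ets_pos_up`;
#' (ns, dn) `ets_pos_dn`; (up, up) `both_up`; (ns, ns) `removed` (not
#' different from normal in either stratum, i.e. subtracted); the
#' remaining patterns (dn, dn), (up, dn), (dn, up) are reported as
#' `other_pattern` rather than silently dropped. Non-target genes are
#' excluded from the output.
#'
#' @param targets Target-annotation `data.frame` from
#'   [annotate_targets()] (columns `gene_id`, `is_target`), or a
#'   character vector of AR-target gene ids.
#' @param dir_neg,dir_pos Direction tables from [tumor_vs_normal()] for
#'   the ETS- and ETS+ strata; they must cover every AR-target gene.
#' @return A `data.frame` with columns `gene_id`, `category`,
#'   `ets_neg_vs_normal` and `ets_pos_vs_normal`.
#' @export
assign_categories <- function(targets, dir_neg, dir_pos) {
  if (is.character(targets)) {
    targets <- data.frame(
      gene_id = targets, is_target = TRUE,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("gene_id", "is_target") %in% names(targets)))
  target_genes <- targets$gene_id[targets$is_target]
  for (nm in c("dir_neg", "dir_pos")) {
    d <- get(nm)
    extra <- setdiff(d$gene_id, targets$gene_id)
    if (length(extra)) {
      abort(
        "gene '", extra[1L], "' present in ", nm,
        " but absent from the target flags"
      )
    }
  }
  miss <- setdiff(target_genes, intersect(dir_neg$gene_id, dir_pos$gene_id))
  if (length(miss)) {
    abort("AR-target gene '", miss[1L], "' lacks a direction in one stratum")
  }
  dn <- dir_neg$direction[match(target_genes, dir_neg$gene_id)]
  dp <- dir_pos$direction[match(target_genes, dir_pos$gene_id)]
  key <- paste(dn, dp, sep = ",")
  category <- c(
    "up,ns" = "ets_neg_up", "dn,ns" = "ets_neg_dn",
    "ns,up" = "ets_pos_up", "ns,dn" = "ets_pos_dn",
    "up,up" = "both_up", "ns,ns" = "removed"
  )[key]
  category[is.na(category)] <- "other_pattern"
  data.frame(
    gene_id = target_genes,
    category = unname(category),
    ets_neg_vs_normal = dn,
    ets_pos_vs_normal = dp,
    stringsAsFactors = FALSE
  )
}

#' Normalize each gene to its median in adjacent normal tissue
#'
#' Heatmap-style normalization: subtracts, per gene, the median log2
#' expression over the adjacent-normal samples, so normals center at 0
#' and tumor values read as log2 differences from normal prostate.
#'
#' @param expr An [expr_matrix()].
#' @param annotation Annotation `data.frame`; its `adjacent_normal`
#'   samples present in the matrix define the reference.
#' @return An [expr_matrix()] of the same shape and platform.
#' @export
normal_median_normalize <- function(expr, annotation) {
  stopifnot(inherits(expr, "expr_matrix"))
  validate_annotation(annotation)
  nrm <- intersect(
    annotation$sample_id[annotation$tissue == "adjacent_normal"],
    sample_ids(expr)
  )
  if (!length(nrm)) abort("no adjacent_normal samples in the matrix")
  med <- apply(expr$values[, nrm, drop = FALSE], 1L, stats::median)
  expr_matrix(expr$values - med, expr$platform)
}
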