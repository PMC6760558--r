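#' Configuration for the end-to-end synthetic pipeline run
#'
#' Bundles the settings of every stage: the synthetic study to
#' generate, per-cohort differential-expression thresholds, the ETS
#' subtyping rule and whether to use it (or trust the annotation's
#' labels), AR-target annotation parameters, the gene-set collection
#' for enrichment and signature scoring, and the random-null and
#' survival settings.
#'
#' @param sim A [simulation_config()] describing the study to generate.
#' @param n_decoys AR-bound tumor-equal-normal decoy genes to flag via
#'   [plant_decoys()].
#' @param ets_source `"call"` to re-derive ETS status from marker
#'   outlier expression (exercising the subtyping stage), or
#'   `"annotation"` to use the labels shipped with the annotation.
#' @param de_rnaseq,de_microarray [de_config()]s per cohort; `NULL`
#'   fold-change minima resolve to the platform defaults (0.585 /
#'   0.05).
#' @param subtyping A [subtyping_rule()].
#' @param annotation An [annotation_params()].
#' @param gene_sets A [gene_set_collection()] for enrichment and
#'   scoring, or `NULL` to build one matched to the simulated truth
#'   with [make_gene_sets()].
#' @param signature_set Name of the set to score and carry into the
#'   biochemical-recurrence analysis.
#' @param n_null Random gene sets for the signature null.
#' @param seed Master seed for the stochastic analysis stages (the
#'   simulation uses `sim$seed`); defaults to `sim$seed + 1`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            n_decoys = 29L,
                            ets_source = c("call", "annotation"),
                            de_rnaseq = de_config(),
                            de_microarray = de_config(),
                            subtyping = subtyping_rule(),
                            annotation = annotation_params(),
                            gene_sets = NULL,
                            signature_set = "SIGNATURE_PATHWAY",
                            n_null = 1000,
                            seed = NULL) {
  ets_source <- match.arg(ets_source)
  stopifnot(
    inherits(sim, "sim_config"), inherits(de_rnaseq, "de_config"),
    inherits(de_microarray, "de_config"), inherits(subtyping, "subtyping_rule"),
    inherits(annotation, "annotation_params")
  )
  if (!is.null(gene_sets)) stopifnot(inherits(gene_sets, "gene_set_collection"))
  if (!is_count(n_decoys, min = 0L)) abort("`n_decoys` must be >= 0")
  if (is.null(seed)) seed <- sim$seed + 1L
  structure(
    list(
      sim = sim, n_decoys = n_decoys, ets_source = ets_source,
      de_rnaseq = de_rnaseq, de_microarray = de_microarray,
      subtyping = subtyping, annotation = annotation,
      gene_sets = gene_sets, signature_set = signature_set,
      n_null = n_null, seed = seed
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full ETS-dependent AR program pipeline on a synthetic study
#'
#' Orchestrates the complete chain on generated data with known ground
#' truth: simulate the two-cohort study (plus decoys), call or adopt
#' ETS status, test differential expression per cohort, intersect the
#' cohorts concordantly, annotate direct AR targets by binding-site
#' proximity, subtract targets indistinguishable from adjacent normal
#' and categorize the survivors, run over-representation analysis of
#' the up-lists, score the designated pathway signature with its
#' random-gene null, and test biochemical recurrence by median score
#' split within each ETS stratum. Every stage's inputs, thresholds and
#' seeds are recorded in a run manifest, and the stage-by-stage funnel
#' counts in a summary table.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created if needed. Stage tables are
#'   written as TSV, the manifest as YAML.
#' @return An object of class `ets_pipeline_result` (invisibly): a list
#'   with every stage result (`sim`, `annotation`, `de`, `concordance`,
#'   `targets`, `categories`, `normalized`, `enrichment`, `signature`,
#'   `bcr`) plus `summary` (named funnel counts) and `manifest`.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- run_stage("simulate", {
    s <- simulate_cohort(config$sim)
    plant_decoys(s, config$n_decoys)
  })

  annotation <- sim$annotation
  ets_accuracy <- NA_real_
  if (config$ets_source == "call") {
    subtyped <- run_stage("subtype", {
      called <- annotation
      platform_of <- c(cohort_rnaseq = "rnaseq", cohort_array = "microarray")
      for (co in unique(annotation$cohort)) {
        expr <- sim$expr[[platform_of[[co]]]]
        sub_ann <- annotation[annotation$cohort == co, ]
        calls <- call_ets_status(expr, config$subtyping, annotation = sub_ann)
        called <- apply_ets_calls(called, calls, overwrite = TRUE)
      }
      tum <- annotation$tissue == "tumor"
      list(
        annotation = called,
        accuracy = mean(called$ets_status[tum] == annotation$ets_status[tum])
      )
    })
    ets_accuracy <- subtyped$accuracy
    annotation <- subtyped$annotation
  }

  de <- run_stage("differential_expression", list(
    rnaseq = run_de(sim$expr$rnaseq, annotation, config$de_rnaseq),
    microarray = run_de(sim$expr$microarray, annotation, config$de_microarray)
  ))

  concordance <- run_stage(
    "intersect_cohorts",
    intersect_cohorts(de$rnaseq, de$microarray)
  )

  targets <- run_stage(
    "ar_target_annotation",
    annotate_targets(sim$gene_models, sim$sites, config$annotation)
  )
  target_genes <- targets$gene_id[targets$is_target]
  funnel_genes <- intersect(concordance$overlap_genes, target_genes)

  categories <- run_stage("category_assignment", {
    if (length(funnel_genes) < 1L) abort("no AR-target genes in the overlap")
    dir_neg <- tumor_vs_normal(sim$expr$rnaseq, annotation, "ets_neg",
      config$de_rnaseq,
      genes = funnel_genes
    )
    dir_pos <- tumor_vs_normal(sim$expr$rnaseq, annotation, "ets_pos",
      config$de_rnaseq,
      genes = funnel_genes
    )
    assign_categories(funnel_genes, dir_neg, dir_pos)
  })

  normalized <- run_stage("normal_median_normalize", {
    kept <- categories$gene_id[categories$category != "removed"]
    if (length(kept)) {
      normal_median_normalize(
        subset_expr(sim$expr$rnaseq, genes = kept), annotation
      )
    } else {
      NULL
    }
  })

  gene_sets <- config$gene_sets
  if (is.null(gene_sets)) gene_sets <- run_stage("gene_sets", make_gene_sets(sim))

  enrichment <- run_stage("enrichment", {
    universe <- gene_ids(sim$expr$rnaseq)
    up_pos <- intersect(
      concordance$overlap_genes,
      de$rnaseq$gene_id[de$rnaseq$direction == "up_in_ets_pos"]
    )
    up_neg <- intersect(
      concordance$overlap_genes,
      de$rnaseq$gene_id[de$rnaseq$direction == "up_in_ets_neg"]
    )
    out <- list()
    if (length(up_pos)) out$up_ets_pos <- run_ora(up_pos, universe, gene_sets)
    if (length(up_neg)) out$up_ets_neg <- run_ora(up_neg, universe, gene_sets)
    out
  })

  signature <- run_stage("signature_scoring", {
    if (!config$signature_set %in% names(gene_sets$sets)) {
      abort("signature set '", config$signature_set, "' not in the collection")
    }
    tumors <- annotation$sample_id[annotation$tissue == "tumor" &
      annotation$cohort == "cohort_rnaseq"]
    signature_score(
      subset_expr(sim$expr$rnaseq, samples = tumors),
      gene_sets$sets[[config$signature_set]],
      set_name = config$signature_set,
      n_null = config$n_null, seed = config$seed
    )
  })

  bcr <- run_stage("survival_analysis", {
    out <- list()
    for (st in c("ets_pos", "ets_neg")) {
      ids <- annotation$sample_id[annotation$tissue == "tumor" &
        annotation$ets_status == st &
        annotation$cohort == "cohort_rnaseq"]
      sc <- signature$sample_scores[intersect(ids, names(signature$sample_scores))]
      out[[st]] <- bcr_analysis(sc, sim$survival)
    }
    out
  })

  cat_counts <- table(factor(categories$category, levels = .category_levels))
  summary <- c(
    n_genes = config$sim$n_genes,
    n_de_rnaseq = sum(de$rnaseq$direction != "ns"),
    pct_de_rnaseq = round(100 * mean(de$rnaseq$direction != "ns"), 1),
    n_de_microarray = sum(de$microarray$direction != "ns"),
    pct_de_microarray = round(100 * mean(de$microarray$direction != "ns"), 1),
    n_overlap = concordance$n_overlap,
    n_up_ets_pos = concordance$n_up_ets_pos,
    n_up_ets_neg = concordance$n_up_ets_neg,
    fc_correlation = round(concordance$fc_correlation, 4),
    n_ar_targets = length(target_genes),
    n_overlap_targets = length(funnel_genes),
    n_removed = unname(cat_counts[["removed"]]),
    n_categorized = nrow(categories) - unname(cat_counts[["removed"]]),
    stats::setNames(
      as.numeric(cat_counts[.categories]),
      paste0("n_", .categories)
    ),
    sig_pc1_var_pct = round(100 * signature$pc1_var_frac, 1),
    sig_null_pc1_percentile = signature$null_pc1_percentile,
    sig_pc_ratio = round(signature$pc_ratio, 2),
    logrank_p_ets_pos = bcr$ets_pos$logrank$p,
    logrank_p_ets_neg = bcr$ets_neg$logrank$p,
    ets_call_accuracy = round(ets_accuracy, 4)
  )

  manifest <- list(
    package = "etsar",
    version = as.character(utils::packageVersion("etsar")),
    seeds = list(simulation = config$sim$seed, analysis = config$seed),
    simulation = unclass(config$sim),
    n_decoys = config$n_decoys,
    ets_source = config$ets_source,
    subtyping = list(
      markers = config$subtyping$marker_genes,
      method = config$subtyping$threshold_method, k = config$subtyping$k
    ),
    thresholds = list(
      rnaseq = list(
        q_max = config$de_rnaseq$q_max,
        fc_min = resolve_fc_min(config$de_rnaseq, "rnaseq")
      ),
      microarray = list(
        q_max = config$de_microarray$q_max,
        fc_min = resolve_fc_min(config$de_microarray, "microarray")
      )
    ),
    ar_annotation = unclass(config$annotation),
    signature = list(
      set = config$signature_set, n_null = config$n_null,
      survival_split = "median; ties to low"
    )
  )

  run_stage("write_outputs", {
    write_tsv(de$rnaseq, file.path(out_dir, "de_rnaseq.tsv"))
    write_tsv(de$microarray, file.path(out_dir, "de_microarray.tsv"))
    write_tsv(
      data.frame(gene_id = concordance$overlap_genes),
      file.path(out_dir, "overlap.tsv")
    )
    write_tsv(targets, file.path(out_dir, "targets.tsv"))
    write_tsv(categories, file.path(out_dir, "categories.tsv"))
    if (!is.null(normalized)) {
      write_expression(normalized, file.path(out_dir, "heatmap_matrix.tsv"))
    }
    for (nm in names(enrichment)) {
      write_tsv(enrichment[[nm]], file.path(out_dir, paste0("enrichment_", nm, ".tsv")))
    }
    write_tsv(
      data.frame(
        sample_id = names(signature$sample_scores),
        score = unname(signature$sample_scores)
      ),
      file.path(out_dir, paste0("scores_", config$signature_set, ".tsv"))
    )
    for (st in names(bcr)) {
      for (g in c("high", "low")) {
        km <- bcr[[st]]$km[[g]]
        write_tsv(
          data.frame(
            time_months = km$times, survival = km$survival,
            at_risk = km$at_risk, events = km$events
          ),
          file.path(out_dir, sprintf(
            "km_%s_%s_%s.tsv", config$signature_set, st, g
          ))
        )
      }
    }
    write_tsv(
      data.frame(stat = names(summary), value = unname(summary)),
      file.path(out_dir, "summary.tsv")
    )
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  })

  invisible(structure(
    list(
      sim = sim, annotation = annotation, de = de,
      concordance = concordance, targets = targets,
      categories = categories, normalized = normalized,
      enrichment = enrichment, signature = signature, bcr = bcr,
      summary = summary, manifest = manifest, out_dir = out_dir
    ),
    class = "ets_pipeline_result"
  ))
}

#' @export
print.ets_pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<ets_pipeline_result>\n")
  cat(sprintf(
    "  DE: %d rnaseq (%.1f%%), %d microarray (%.1f%%) of %d genes\n",
    s[["n_de_rnaseq"]], s[["pct_de_rnaseq"]],
    s[["n_de_microarray"]], s[["pct_de_microarray"]], s[["n_genes"]]
  ))
  cat(sprintf(
    "  overlap: %d (%d up ETS+, %d up ETS-); log2FC r = %.3f\n",
    s[["n_overlap"]], s[["n_up_ets_pos"]], s[["n_up_ets_neg"]],
    s[["fc_correlation"]]
  ))
  cat(sprintf(
    "  AR targets: %d; in overlap: %d; removed vs normal: %d; categorized: %d\n",
    s[["n_ar_targets"]], s[["n_overlap_targets"]],
    s[["n_removed"]], s[["n_categorized"]]
  ))
  cat(sprintf(
    "  signature PC1: %.1f%% var (null pctl %.2f); log-rank p ETS+ %.3g, ETS- %.3g\n",
    s[["sig_pc1_var_pct"]], s[["sig_null_pc1_percentile"]],
    s[["logrank_p_ets_pos"]], s[["logrank_p_ets_neg"]]
  ))
  invisible(x)
}
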