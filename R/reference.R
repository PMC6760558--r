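#' Reference study design emulated by the synthetic generator
#'
#' The cohort characteristics and analysis funnel of the reference
#' prostate-cancer study design this pipeline is modeled on: an RNA-seq
#' tumor cohort and two registry-scale microarray cohorts profiled for
#' ETS status, a differential-expression funnel narrowing genome-wide tests
#' to a concordant cross-cohort overlap, then to direct AR targets, and
#' finally — after subtracting targets indistinguishable from adjacent
#' normal tissue — to the categorized ETS-dependent AR program. These
#' numbers are the design the simulator emulates at reduced scale and
#' the yardstick for arithmetic-consistency checks; they are not
#' recomputed by the package.
#'
#' @return A nested list with elements `cohorts` (per-cohort sample and
#'   gene counts and differential-gene counts), `funnel` (overlap and
#'   subtraction counts) and `signatures` (PC1 coherence statistics of
#'   the two outcome-associated pathway signatures and the size of the
#'   androgen-response reference set).
#' @export
reference_design <- function() {
  list(
    cohorts = list(
      rnaseq = list(
        n_tumor = 333, n_ets_pos = 198, n_ets_neg = 135,
        n_genes = 20531, n_de = 1423, de_pct = 6.9, fc_min = 0.585
      ),
      microarray = list(
        n_tumor = 635, n_ets_pos = 326, n_ets_neg = 309,
        n_genes = 46050, n_de = 3047, de_pct = 6.6, fc_min = 0.05
      ),
      microarray_prospective = list(
        n_tumor = 9640, n_ets_pos = 4883, n_ets_neg = 4757
      )
    ),
    funnel = list(
      n_overlap = 413, n_up_ets_pos = 220, n_up_ets_neg = 193,
      n_ar_targets = 160, n_removed = 29, n_categorized = 131
    ),
    signatures = list(
      androgen_response_size = 101,
      non_canonical_wnt = list(
        pc1_var_pct = 55.9, pc1_null_pct = 99.6,
        pc_ratio = 3.3, ratio_null_pct = 99.99
      ),
      metabolic = list(
        pc1_var_pct = 51.5, pc1_null_pct = 99.99,
        pc_ratio = 5.9, ratio_null_pct = 99.99
      ),
      median_followup_months = 24
    )
  )
}

#' Arithmetic consistency of a study-design funnel
#'
#' Recomputes the derivable quantities of a [reference_design()]-shaped
#' design: per-cohort differential percentages from counts, the ETS
#' stratum sums, the up-in-ETS+ / up-in-ETS- partition of the overlap,
#' and the subtraction identity (targets minus removed equals
#' categorized).
#'
#' @param design A list shaped like [reference_design()].
#' @return A list of recomputed values: `de_pct` per cohort (rounded to
#'   one decimal), `stratum_sum` per cohort, `overlap_sum`,
#'   `post_subtraction`.
#' @export
design_arithmetic <- function(design) {
  pct <- function(co) round(100 * co$n_de / co$n_genes, 1)
  with_de <- Filter(function(co) !is.null(co$n_de), design$cohorts)
  list(
    de_pct = vapply(with_de, pct, numeric(1)),
    stratum_sum = vapply(
      design$cohorts,
      function(co) co$n_ets_pos + co$n_ets_neg, numeric(1)
    ),
    overlap_sum = design$funnel$n_up_ets_pos + design$funnel$n_up_ets_neg,
    post_subtraction = design$funnel$n_ar_targets - design$funnel$n_removed
  )
}
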