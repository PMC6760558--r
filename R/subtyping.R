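#' Rule for calling ETS status from marker-gene expression
#'
#' ETS-positive prostate tumors overexpress the ETS-family transcription
#' factor captured by their gene fusion (typically TMPRSS2-ERG), so ETS
#' status can be called from outlier expression of the marker panel.
#' With `threshold_method = "mad_outlier"` the per-marker cut-point is
#' `median + k * MAD` over a reference sample set (MAD scaled by the
#' usual 1.4826 consistency constant, as in [stats::mad()]). A `fixed`
#' mode accepts externally supplied per-marker cut-points, e.g. to
#' reproduce labels shipped with a dataset.
#'
#' The reference matters: fusions are tumor-specific, and in prostate
#' cancer roughly half of all tumors are ETS-positive, enough one-sided
#' contamination to inflate a tumor-derived MAD until no outlier clears
#' `median + k * MAD`. Adjacent-normal samples are fusion-free, so they
#' are the default reference whenever the annotation identifies enough
#' of them; otherwise the cut-points fall back to the tumor samples
#' themselves (adequate only when the ETS-positive fraction is well
#' below half).
#'
#' @param marker_genes ETS-family marker panel.
#' @param threshold_method `"mad_outlier"` or `"fixed"`.
#' @param k MAD multiplier for the outlier cut-point.
#' @param min_reference Minimum adjacent-normal samples required to use
#'   them as the reference before falling back to tumors.
#' @param fixed_cutpoints Named numeric vector of per-marker cut-points;
#'   required for `"fixed"`, and used as fallback for markers whose MAD
#'   is zero under `"mad_outlier"`.
#' @return An object of class `subtyping_rule`.
#' @export
subtyping_rule <- function(marker_genes = c("ERG", "ETV1", "ETV4", "ETV5", "FLI1"),
                           threshold_method = c("mad_outlier", "fixed"),
                           k = 3,
                           min_reference = 5L,
                           fixed_cutpoints = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (!is.character(marker_genes) || !length(marker_genes)) {
    abort("`marker_genes` must be a non-empty character vector")
  }
  if (!is_number(k) || k <= 0) abort("`k` must be a positive number")
  if (!is_count(min_reference, min = 2L)) abort("`min_reference` must be >= 2")
  if (threshold_method == "fixed") {
    if (is.null(fixed_cutpoints) || is.null(names(fixed_cutpoints)) ||
      !all(marker_genes %in% names(fixed_cutpoints))) {
      abort("`fixed` thresholding needs `fixed_cutpoints` covering every marker")
    }
  }
  structure(
    list(
      marker_genes = marker_genes, threshold_method = threshold_method,
      k = k, min_reference = min_reference, fixed_cutpoints = fixed_cutpoints
    ),
    class = "subtyping_rule"
  )
}

#' Call ETS status for tumor samples from marker overexpression
#'
#' A tumor is called `ets_pos` if any marker exceeds its cut-point; the
#' driving marker is the one with the largest exceedance (in MAD units
#' for the outlier rule). All other tumors are called `ets_neg`, so the
#' calls partition the tumor samples. Raising a sample's marker value
#' can only move it toward (never away from) an `ets_pos` call.
#'
#' @param expr An [expr_matrix()]. Without `annotation`, every column
#'   is treated as a tumor sample and the cut-point reference.
#' @param rule A [subtyping_rule()].
#' @param annotation Optional annotation `data.frame`; when supplied,
#'   only its `tissue == "tumor"` samples are called, and its
#'   `adjacent_normal` samples (if at least `rule$min_reference` are in
#'   the matrix) anchor the cut-points.
#' @return A `data.frame` with columns `sample_id`, `ets_status`,
#'   `driving_marker` (NA for `ets_neg` calls) and `exceedance` (the
#'   driver's distance above its cut-point, in scale units).
#' @export
call_ets_status <- function(expr, rule = subtyping_rule(), annotation = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(rule, "subtyping_rule"))
  tumors <- sample_ids(expr)
  reference <- sample_ids(expr)
  if (!is.null(annotation)) {
    validate_annotation(annotation)
    tumors <- intersect(
      annotation$sample_id[annotation$tissue == "tumor"],
      sample_ids(expr)
    )
    if (!length(tumors)) abort("no tumor samples shared between matrix and annotation")
    normals <- intersect(
      annotation$sample_id[annotation$tissue == "adjacent_normal"],
      sample_ids(expr)
    )
    reference <- if (length(normals) >= rule$min_reference) normals else tumors
  }
  missing <- setdiff(rule$marker_genes, gene_ids(expr))
  if (length(missing)) {
    abort("marker gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  ref_vals <- expr$values[rule$marker_genes, reference, drop = FALSE]
  vals <- expr$values[rule$marker_genes, tumors, drop = FALSE]

  cutpoint <- numeric(length(rule$marker_genes))
  scale <- numeric(length(rule$marker_genes))
  names(cutpoint) <- names(scale) <- rule$marker_genes
  for (m in rule$marker_genes) {
    if (rule$threshold_method == "fixed") {
      cutpoint[m] <- rule$fixed_cutpoints[[m]]
      scale[m] <- 1
    } else {
      mad_m <- stats::mad(ref_vals[m, ])
      if (mad_m == 0) {
        if (!is.null(rule$fixed_cutpoints) && m %in% names(rule$fixed_cutpoints)) {
          cutpoint[m] <- rule$fixed_cutpoints[[m]]
          scale[m] <- 1
        } else {
          abort("marker '", m, "' has zero MAD and no fixed cut-point fallback")
        }
      } else {
        cutpoint[m] <- stats::median(ref_vals[m, ]) + rule$k * mad_m
        scale[m] <- mad_m
      }
    }
  }

  exceed <- (vals - cutpoint) / scale # markers x samples, in scale units
  any_pos <- apply(exceed > 0, 2L, any)
  driver <- rule$marker_genes[apply(exceed, 2L, which.max)]
  data.frame(
    sample_id = tumors,
    ets_status = ifelse(any_pos, "ets_pos", "ets_neg"),
    driving_marker = ifelse(any_pos, driver, NA_character_),
    exceedance = ifelse(any_pos, apply(exceed, 2L, max), NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Apply ETS calls to an annotation table
#'
#' Writes called statuses into the `ets_status` column for the called
#' samples. By default pre-existing non-`unknown` labels are kept
#' (datasets often ship with curated ETS labels); set
#' `overwrite = TRUE` to replace them with the calls.
#'
#' @param annotation Annotation `data.frame`.
#' @param calls Result of [call_ets_status()].
#' @param overwrite Replace existing non-unknown labels?
#' @return The updated annotation `data.frame`.
#' @export
apply_ets_calls <- function(annotation, calls, overwrite = FALSE) {
  validate_annotation(annotation)
  idx <- match(calls$sample_id, annotation$sample_id)
  if (anyNA(idx)) {
    abort(
      "called sample(s) absent from annotation: ",
      calls$sample_id[is.na(idx)][1L]
    )
  }
  replace <- if (overwrite) rep(TRUE, length(idx)) else annotation$ets_status[idx] == "unknown"
  annotation$ets_status[idx[replace]] <- calls$ets_status[replace]
  # a subtype label contradicting an overwritten status is dropped
  clash <- annotation$subtype[idx] %in% .ets_pos_subtypes &
    annotation$ets_status[idx] == "ets_neg" |
    annotation$subtype[idx] %in% .ets_neg_subtypes &
      annotation$ets_status[idx] == "ets_pos"
  annotation$subtype[idx[clash]] <- "none"
  validate_annotation(annotation)
}
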