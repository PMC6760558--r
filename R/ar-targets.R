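#' Parameters for direct AR target annotation
#'
#' A gene is a direct AR target when an AR ChIP-seq binding site lies
#' within `window_bp` of its transcription start site. The default
#' window is 25 kb. `symmetric` mode (the default, and the more common
#' convention) accepts a qualifying site on either side of the TSS;
#' `downstream_only` additionally requires the site to lie 3' of the TSS
#' with respect to the gene's strand. When binding sites are pooled from
#' several ChIP-seq studies, `min_sources` sets how many distinct
#' studies must contribute a qualifying site.
#'
#' @param window_bp Maximum TSS-to-site distance in bp (> 0).
#' @param mode `"symmetric"` or `"downstream_only"`.
#' @param min_sources Minimum number of distinct supporting sources.
#' @return An object of class `annotation_params`.
#' @export
annotation_params <- function(window_bp = 25000,
                              mode = c("symmetric", "downstream_only"),
                              min_sources = 1L) {
  mode <- match.arg(mode)
  if (!is_count(window_bp, min = 1L)) abort("`window_bp` must be a positive integer")
  if (!is_count(min_sources, min = 1L)) abort("`min_sources` must be a positive integer")
  structure(
    list(window_bp = window_bp, mode = mode, min_sources = min_sources),
    class = "annotation_params"
  )
}

#' Annotate genes as direct AR targets by binding-site proximity
#'
#' Distances are measured from the TSS to the nearest edge of each
#' binding site (0 when the site overlaps the TSS); coordinates are
#' 0-based half-open throughout. A gene whose chromosome carries no
#' sites is simply a non-target. The result does not depend on the
#' ordering of `sites`, and enlarging the window can only add targets.
#'
#' @param genes Gene-model `data.frame` (`gene_id`, `chrom`, `tss`,
#'   `strand`); see [read_gene_models()].
#' @param sites Binding-site `data.frame` (`chrom`, `start`, `end`,
#'   `source`); see [read_bed()].
#' @param params An [annotation_params()].
#' @return A `data.frame` with one row per gene: `gene_id`, `is_target`,
#'   `n_supporting_sources` (distinct sources with a qualifying site)
#'   and `min_distance_bp` (distance to the nearest site on the gene's
#'   chromosome regardless of qualification; `NA` if none).
#' @export
annotate_targets <- function(genes, sites, params = annotation_params()) {
  validate_gene_models(genes)
  stopifnot(inherits(params, "annotation_params"))
  if (!all(c("chrom", "start", "end") %in% names(sites))) {
    abort("`sites` must have columns chrom, start, end")
  }
  if (is.null(sites$source)) sites$source <- "unspecified"
  if (any(sites$start >= sites$end)) abort("binding sites must satisfy start < end")

  by_chrom <- split(sites, sites$chrom)
  out <- data.frame(
    gene_id = genes$gene_id,
    is_target = FALSE,
    n_supporting_sources = 0L,
    min_distance_bp = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(genes))) {
    ss <- by_chrom[[genes$chrom[i]]]
    if (is.null(ss) || !nrow(ss)) next
    tss <- genes$tss[i]
    dist <- ifelse(ss$start > tss, ss$start - tss,
      ifelse(ss$end <= tss, tss - ss$end, 0L)
    )
    qual <- dist <= params$window_bp
    if (params$mode == "downstream_only") {
      downstream <- dist == 0L |
        (genes$strand[i] == "+" & ss$start > tss) |
        (genes$strand[i] == "-" & ss$end <= tss)
      qual <- qual & downstream
    }
    out$min_distance_bp[i] <- min(dist)
    out$n_supporting_sources[i] <- length(unique(ss$source[qual]))
    out$is_target[i] <- out$n_supporting_sources[i] >= params$min_sources
  }
  out
}
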