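#' First-principal-component signature score
#'
#' Summarizes a gene set per sample by the first principal component of
#' the set's expression submatrix. Genes are mean-centered across
#' samples but not variance-standardized (covariance PCA), and the
#' component sign is oriented so that scores correlate positively with
#' the set's mean centered expression. The fraction of variance
#' explained by PC1 and the PC1/PC2 variance ratio are the coherence
#' statistics calibrated by [random_set_null()].
#'
#' @param expr An [expr_matrix()] with at least 3 samples.
#' @param gene_set Character vector of gene ids; at least 2 must be
#'   present in the matrix.
#' @param standardize Scale each gene to unit variance before the
#'   decomposition (correlation PCA) instead of the default covariance
#'   PCA.
#' @return A list with `sample_scores` (named numeric vector),
#'   `pc1_var_frac`, `pc_ratio` and `n_genes_used`.
#' @export
pc1_score <- function(expr, gene_set, standardize = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  present <- intersect(gene_set, gene_ids(expr))
  if (length(present) < 2L) {
    abort("need >= 2 genes of the set in the matrix (got ", length(present), ")")
  }
  if (ncol(expr$values) < 3L) abort("need >= 3 samples")
  x <- expr$values[present, , drop = FALSE]
  x <- x - rowMeans(x)
  if (standardize) {
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0)) abort("zero-variance gene under standardization")
    x <- x / sds
  }
  if (all(x == 0)) abort("zero-variance submatrix: no principal components")
  sv <- svd(x)
  d2 <- sv$d^2
  scores <- sv$d[1L] * sv$v[, 1L]
  # orient PC1 along the set's mean expression profile
  mean_profile <- colMeans(x)
  s <- sum(scores * mean_profile)
  if (s < 0 || (s == 0 && sum(sv$u[, 1L]) < 0)) scores <- -scores
  names(scores) <- colnames(x)
  list(
    sample_scores = scores,
    pc1_var_frac = d2[1L] / sum(d2),
    pc_ratio = if (length(d2) > 1L && d2[2L] > 0) d2[1L] / d2[2L] else Inf,
    n_genes_used = length(present)
  )
}

#' Random-gene-set null for PC1 coherence statistics
#'
#' Draws `n_null` gene sets of the observed size uniformly (without
#' replacement within a draw) from all genes in the matrix, scores each
#' with [pc1_score()], and returns the empirical null distributions of
#' the PC1 variance fraction and of the PC1/PC2 variance ratio. A real
#' pathway signature should sit in the extreme upper tail of both.
#'
#' @param expr An [expr_matrix()].
#' @param set_size Genes per random draw.
#' @param n_null Number of draws (>= 100 so tail percentiles resolve).
#' @param seed Seed for the draws (mandatory, for reproducibility).
#' @param standardize Passed to [pc1_score()].
#' @return A list of class `pc1_null` with `pc1_var_frac` and
#'   `pc_ratio` (numeric vectors of length `n_null`), plus `set_size`,
#'   `n_null` and `seed`.
#' @export
random_set_null <- function(expr, set_size, n_null = 10000, seed, standardize = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (missing(seed) || !is_count(abs(seed), min = 0L)) {
    abort("`seed` is required and must be an integer")
  }
  if (!is_count(set_size, min = 2L)) abort("`set_size` must be an integer >= 2")
  if (set_size > length(gene_ids(expr))) {
    abort("`set_size` exceeds the number of genes in the matrix")
  }
  if (!is_count(n_null, min = 100L)) abort("`n_null` must be an integer >= 100")
  genes <- gene_ids(expr)
  pc1 <- numeric(n_null)
  ratio <- numeric(n_null)
  with_stream(seed, 1L, {
    for (i in seq_len(n_null)) {
      draw <- sample(genes, set_size)
      sc <- pc1_score(expr, draw, standardize = standardize)
      pc1[i] <- sc$pc1_var_frac
      ratio[i] <- sc$pc_ratio
    }
  })
  structure(
    list(
      pc1_var_frac = pc1, pc_ratio = ratio,
      set_size = set_size, n_null = n_null, seed = seed
    ),
    class = "pc1_null"
  )
}

#' Percentile of an observed value within a null distribution
#'
#' Fraction of null values strictly below the observation, times 100.
#' Ties therefore resolve toward the conservative (lower) percentile.
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null draws.
#' @return Percentile in \[0, 100\].
#' @export
null_percentile <- function(observed, null) {
  if (!is_number(observed) && !is.infinite(observed)) abort("`observed` must be numeric")
  100 * mean(null < observed)
}

#' Score a pathway signature and calibrate it against random gene sets
#'
#' Convenience wrapper combining [pc1_score()] on the observed set with
#' [random_set_null()] of matched size, reporting where the observed
#' PC1 variance fraction and PC1/PC2 ratio fall within the null.
#'
#' @param expr An [expr_matrix()].
#' @param gene_set Character vector of signature gene ids.
#' @param set_name Label carried in the result.
#' @param n_null Random sets to draw.
#' @param seed Seed for the null draws.
#' @param standardize Passed to [pc1_score()].
#' @return A list of class `signature_score`: `set_name`,
#'   `sample_scores`, `pc1_var_frac`, `pc_ratio`,
#'   `null_pc1_percentile`, `null_ratio_percentile`, `n_null`, `seed`.
#' @export
signature_score <- function(expr, gene_set, set_name = "signature",
                            n_null = 10000, seed, standardize = FALSE) {
  obs <- pc1_score(expr, gene_set, standardize = standardize)
  null <- random_set_null(expr, obs$n_genes_used,
    n_null = n_null, seed = seed,
    standardize = standardize
  )
  structure(
    list(
      set_name = set_name,
      sample_scores = obs$sample_scores,
      pc1_var_frac = obs$pc1_var_frac,
      pc_ratio = obs$pc_ratio,
      null_pc1_percentile = null_percentile(obs$pc1_var_frac, null$pc1_var_frac),
      null_ratio_percentile = null_percentile(obs$pc_ratio, null$pc_ratio),
      n_null = n_null, seed = seed
    ),
    class = "signature_score"
  )
}

#' @export
print.signature_score <- function(x, ...) {
  cat("<signature_score> '", x$set_name, "': PC1 explains ",
    sprintf("%.1f%%", 100 * x$pc1_var_frac),
    " of variance (better than ", sprintf("%.2f%%", x$null_pc1_percentile),
    " of ", x$n_null, " random models); PC1/PC2 = ",
    sprintf("%.2f", x$pc_ratio),
    " (better than ", sprintf("%.2f%%", x$null_ratio_percentile), ")\n",
    sep = ""
  )
  invisible(x)
}
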