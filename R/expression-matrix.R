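#' Expression matrix container
#'
#' A light container for a genes-by-samples matrix of log2 expression
#' values together with the profiling platform it came from. The platform
#' tag matters downstream: fold-change thresholds differ between RNA-seq
#' derived values and compressed microarray (SCAN-style) values, so every
#' differential-expression stage consults it for its default cut-off.
#'
#' @param values Numeric matrix, genes as rows and samples as columns.
#'   Row names are gene identifiers, column names sample identifiers;
#'   both must be unique and all values finite (missing values are not
#'   supported anywhere in the pipeline).
#' @param platform Either `"rnaseq"` or `"microarray"`.
#'
#' @return An object of class `expr_matrix` with elements `values` and
#'   `platform`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("KLK3", "ERG"), c("s1", "s2", "s3")))
#' em <- expr_matrix(m, "rnaseq")
#' gene_ids(em)
#' @export
expr_matrix <- function(values, platform = c("rnaseq", "microarray")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values))) abort("`values` must have gene ids as row names")
  if (is.null(colnames(values))) abort("`values` must have sample ids as column names")
  dup <- first_dup(rownames(values))
  if (!is.null(dup)) abort("duplicate gene id: '", dup, "'")
  dup <- first_dup(colnames(values))
  if (!is.null(dup)) abort("duplicate sample id: '", dup, "'")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    abort(
      "non-finite expression value at gene '", rownames(values)[bad[1L]],
      "', sample '", colnames(values)[bad[2L]], "'"
    )
  }
  structure(list(values = values, platform = platform), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(
    "<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
    " samples [", x$platform, "]\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  rownames(x$values)
}

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  colnames(x$values)
}

# Subset an expr_matrix by gene and/or sample ids, preserving the class.
subset_expr <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) {
      abort("gene id(s) absent from matrix: ", paste(missing, collapse = ", "))
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) {
      abort("sample id(s) absent from matrix: ", paste(missing, collapse = ", "))
    }
    v <- v[, samples, drop = FALSE]
  }
  expr_matrix(v, x$platform)
}
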