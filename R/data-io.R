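#' Read a genes-by-samples expression matrix from TSV
#'
#' The expected layout is one header row of sample identifiers, one row
#' per gene, and the gene identifier in the first column. All expression
#' values must parse as finite numbers; the readers deliberately reject
#' missing or non-numeric cells because no stage of the pipeline defines
#' behaviour for them.
#'
#' @param path Path to a tab-separated file.
#' @param platform Platform tag recorded on the returned matrix,
#'   `"rnaseq"` or `"microarray"`.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, platform = c("rnaseq", "microarray")) {
  platform <- match.arg(platform)
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    stringsAsFactors = FALSE, colClasses = "character", quote = ""
  )
  if (ncol(df) < 2L) abort("expression file needs a gene id column plus >=1 sample column")
  ids <- df[[1L]]
  dup <- first_dup(ids)
  if (!is.null(dup)) abort("duplicate gene id in '", path, "': '", dup, "'")
  dup <- first_dup(colnames(df)[-1L])
  if (!is.null(dup)) abort("duplicate sample id in '", path, "': '", dup, "'")
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(
      "non-numeric expression value '", raw[bad[1L, 1L], bad[1L, 2L]],
      "' at gene '", ids[bad[1L, 1L]], "', sample '",
      colnames(raw)[bad[1L, 2L]], "' in '", path, "'"
    )
  }
  dimnames(num) <- list(ids, colnames(raw))
  expr_matrix(num, platform)
}

#' Write an expression matrix as TSV
#'
#' @param x An [expr_matrix()].
#' @param path Output path; the first column is named `gene_id`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

#' Read AR binding sites from a BED file
#'
#' Standard 3+ column BED: chromosome, 0-based start, half-open end.
#' Columns beyond the third are ignored; every record carries a `source`
#' label identifying the ChIP-seq dataset it came from, used when
#' requiring multi-study support for a direct AR target call.
#'
#' @param path Path to a BED file.
#' @param source Dataset label attached to every record; defaults to the
#'   file name without extension.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `source`,
#'   in file order.
#' @export
read_bed <- function(path, source = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(
      chrom = character(), start = integer(), end = integer(),
      source = character(), stringsAsFactors = FALSE
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort("BED line ", which(nf < 3L)[1L], " in '", path, "' has fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L)
  if (length(bad)) {
    abort("BED line ", bad[1L], " in '", path, "' has a malformed coordinate")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    abort(
      "BED line ", bad[1L], " in '", path, "': start (", start[bad[1L]],
      ") must be < end (", end[bad[1L]], ")"
    )
  }
  data.frame(
    chrom = chrom, start = start, end = end,
    source = rep_len(source, length(chrom)), stringsAsFactors = FALSE
  )
}

#' Write binding sites as BED
#'
#' @param sites A binding-site `data.frame` (`chrom`, `start`, `end`,
#'   optionally `source` written as the name column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(sites)))
  cols <- sites[, c("chrom", "start", "end")]
  if ("source" %in% names(sites)) cols$name <- sites$source
  utils::write.table(cols, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Gene-set collection constructor
#'
#' @param name Collection name.
#' @param sets Named list of character vectors of gene ids. Members must
#'   be unique within a set and no set may be empty.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(name, sets) {
  if (!is_string(name)) abort("`name` must be a single string")
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a named list of gene id vectors")
  }
  dup <- first_dup(names(sets))
  if (!is.null(dup)) abort("duplicate set name: '", dup, "'")
  for (s in names(sets)) {
    if (!length(sets[[s]])) abort("set '", s, "' is empty")
    d <- first_dup(sets[[s]])
    if (!is.null(d)) abort("set '", s, "' has duplicate member '", d, "'")
  }
  structure(list(name = name, sets = sets), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(
    "<gene_set_collection> '", x$name, "': ", length(x$sets),
    " sets, sizes ", paste(range(lengths(x$sets)), collapse = "-"), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: set name, description, then members, tab-separated.
#' The description column is discarded. Duplicate members within a set
#' are collapsed with a warning.
#'
#' @param path Path to a GMT file.
#' @param name Collection name; defaults to the file name without
#'   extension.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort("GMT line ", which(nf < 3L)[1L], " in '", path, "' has fewer than 3 fields")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  for (s in names(sets)) {
    if (anyDuplicated(sets[[s]])) {
      warning("GMT set '", s, "' has duplicate members; deduplicated", call. = FALSE)
      sets[[s]] <- unique(sets[[s]])
    }
  }
  gene_set_collection(name, sets)
}

#' Write a gene-set collection as GMT
#'
#' @param x A [gene_set_collection()].
#' @param path Output path. The description column is written as `na`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(
    names(x$sets),
    function(s) paste(c(s, "na", x$sets[[s]]), collapse = "\t"),
    ""
  )
  writeLines(lines, path)
  invisible(path)
}

.tissues <- c("tumor", "adjacent_normal")
.ets_statuses <- c("ets_pos", "ets_neg", "unknown")
.subtypes <- c("ERG", "ETV1", "ETV4", "FLI1", "SPOP", "FOXA1", "IDH1", "other", "none")
.ets_pos_subtypes <- c("ERG", "ETV1", "ETV4", "FLI1")
.ets_neg_subtypes <- c("SPOP", "FOXA1", "IDH1", "other")

#' Validate a cohort annotation table
#'
#' The annotation table carries one row per sample: `sample_id`,
#' `cohort`, `tissue` (tumor / adjacent_normal), `ets_status`
#' (ets_pos / ets_neg / unknown) and molecular `subtype`. Subtype and
#' ETS status must agree: ERG/ETV1/ETV4/FLI1 imply ets_pos, while
#' SPOP/FOXA1/IDH1/other imply ets_neg.
#'
#' @param annot A `data.frame` with the columns above.
#' @return The validated `data.frame` (invisibly usable in pipelines).
#' @export
validate_annotation <- function(annot) {
  req <- c("sample_id", "cohort", "tissue", "ets_status", "subtype")
  missing <- setdiff(req, names(annot))
  if (length(missing)) {
    abort("annotation lacks column(s): ", paste(missing, collapse = ", "))
  }
  dup <- first_dup(annot$sample_id)
  if (!is.null(dup)) abort("duplicate sample id in annotation: '", dup, "'")
  bad <- setdiff(unique(annot$tissue), .tissues)
  if (length(bad)) abort("unknown tissue value: '", bad[1L], "'")
  bad <- setdiff(unique(annot$ets_status), .ets_statuses)
  if (length(bad)) abort("unknown ets_status value: '", bad[1L], "'")
  bad <- setdiff(unique(annot$subtype), .subtypes)
  if (length(bad)) abort("unknown subtype value: '", bad[1L], "'")
  clash <- annot$subtype %in% .ets_pos_subtypes & annot$ets_status == "ets_neg" |
    annot$subtype %in% .ets_neg_subtypes & annot$ets_status == "ets_pos"
  if (any(clash)) {
    abort(
      "sample '", annot$sample_id[which(clash)[1L]],
      "': subtype and ets_status are inconsistent"
    )
  }
  annot
}

#' Read / write a cohort annotation table (TSV)
#'
#' @param path Path to a tab-separated annotation file with columns
#'   `sample_id`, `cohort`, `tissue`, `ets_status`, `subtype`.
#' @return A validated annotation `data.frame`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, quote = ""
  )
  validate_annotation(df)
}

#' @rdname read_annotation
#' @param annot Annotation `data.frame` to write.
#' @export
write_annotation <- function(annot, path) {
  validate_annotation(annot)
  utils::write.table(annot, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read / write gene models (TSS table)
#'
#' Gene models are the minimal BED-like description the target-annotation
#' stage needs: one row per gene with `gene_id`, `chrom`, `tss` (0-based
#' coordinate of the transcription start site) and `strand` (+/-).
#'
#' @param path Path to a tab-separated file with those four columns.
#' @return A `data.frame` of gene models.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, quote = ""
  )
  validate_gene_models(df)
}

#' @rdname read_gene_models
#' @param genes Gene-model `data.frame` to write.
#' @export
write_gene_models <- function(genes, path) {
  validate_gene_models(genes)
  utils::write.table(genes, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' @rdname read_gene_models
#' @export
validate_gene_models <- function(genes) {
  req <- c("gene_id", "chrom", "tss", "strand")
  missing <- setdiff(req, names(genes))
  if (length(missing)) {
    abort("gene models lack column(s): ", paste(missing, collapse = ", "))
  }
  dup <- first_dup(genes$gene_id)
  if (!is.null(dup)) abort("duplicate gene model for '", dup, "'")
  if (any(!is.finite(genes$tss) | genes$tss < 0)) {
    abort("gene '", genes$gene_id[which(genes$tss < 0)[1L]], "' has a negative TSS")
  }
  bad <- setdiff(unique(genes$strand), c("+", "-"))
  if (length(bad)) abort("malformed strand value: '", bad[1L], "'")
  genes
}

#' Read / write biochemical-recurrence survival tables (TSV)
#'
#' Columns: `sample_id`, `time_months` (positive follow-up time to
#' biochemical recurrence or censoring) and `event` (1 = recurrence
#' observed, 0 = censored).
#'
#' @param path Path to a tab-separated survival file.
#' @return A `data.frame` with columns `sample_id`, `time_months`,
#'   `event` (logical).
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, quote = ""
  )
  validate_survival(df)
}

#' @rdname read_survival
#' @param surv Survival `data.frame` to write.
#' @export
write_survival <- function(surv, path) {
  surv <- validate_survival(surv)
  out <- surv
  out$event <- as.integer(out$event)
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' @rdname read_survival
#' @export
validate_survival <- function(surv) {
  req <- c("sample_id", "time_months", "event")
  missing <- setdiff(req, names(surv))
  if (length(missing)) {
    abort("survival table lacks column(s): ", paste(missing, collapse = ", "))
  }
  dup <- first_dup(surv$sample_id)
  if (!is.null(dup)) abort("duplicate sample id in survival table: '", dup, "'")
  if (any(!is.finite(surv$time_months) | surv$time_months <= 0)) {
    abort("survival times must be positive")
  }
  if (!all(surv$event %in% c(0, 1, TRUE, FALSE))) {
    abort("event indicator must be 0/1")
  }
  surv$event <- as.logical(surv$event)
  surv
}
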