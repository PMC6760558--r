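#' Configuration for the synthetic two-cohort study generator
#'
#' Describes a two-cohort prostate-cancer expression study with planted
#' ETS-dependent AR-target structure. The generator emulates: an RNA-seq
#' style cohort and a microarray style cohort measuring the same gene
#' space with platform-specific noise and an affine per-gene distortion
#' (so cross-platform fold changes correlate strongly but not perfectly);
#' outlier overexpression of one ETS-family marker per ETS-positive
#' tumor; AR binding sites within 25 kb of the TSS for designated target
#' genes and at least 50 kb away for all others; and biochemical
#' recurrence times whose hazard follows a planted per-sample pathway
#' activity.
#'
#' @param n_tumor_ets_pos,n_tumor_ets_neg,n_normal Samples per cohort in
#'   each group (each cohort gets its own independent samples).
#' @param n_genes Total genes, including the five ETS marker genes.
#' @param n_per_category Planted genes for each of the five
#'   ETS-dependent AR-target categories (`ets_neg_up`, `ets_neg_dn`,
#'   `ets_pos_up`, `ets_pos_dn`, `both_up`).
#' @param n_extra_both_up Extra planted `both_up` genes beyond
#'   `n_per_category` (lets the planted total be odd, e.g. 5 x 26 + 1).
#' @param effect_size Log2 shift of planted genes in their designated
#'   tumor stratum relative to adjacent normal.
#' @param marker_shift Log2 overexpression of the driving ETS marker in
#'   the tumors it drives. Fusion-driven marker overexpression is an
#'   outlier effect much larger than downstream AR-program shifts (ERG
#'   rises over a hundred-fold in TMPRSS2-ERG tumors), so the default
#'   scales it to four times `effect_size` — large enough to survive
#'   the microarray gain compression as a clear outlier.
#' @param noise_sd Named numeric vector with per-platform residual
#'   standard deviations, names `rnaseq` and `microarray`.
#' @param frac_ar_bound Fraction of genes given an AR binding site within
#'   25 kb of their TSS. All planted category genes are AR-bound; if the
#'   fraction asks for more, additional unshifted genes are bound too.
#' @param n_signature Number of planted genes (drawn from the
#'   `ets_pos_up` and `both_up` categories) that additionally carry a
#'   shared latent pathway activity across tumor samples.
#' @param signature_loading Loading of the latent activity on each
#'   signature gene (log2 units per activity SD).
#' @param hazard_coef Log hazard of biochemical recurrence per unit of
#'   latent pathway activity.
#' @param baseline_hazard Baseline exponential hazard (per month) of
#'   recurrence at activity 0.
#' @param censor_max Upper bound (months) of the independent uniform
#'   censoring time; 48 months yields a median follow-up near 24 months.
#' @param array_gain_mean,array_gain_sd Mean and SD of the per-gene
#'   multiplicative gain applied on the microarray platform (gains are
#'   truncated below at 0.05), emulating the compressed fold-change scale
#'   of SCAN-style microarray normalization.
#' @param seed Master seed. Every output artifact draws from its own RNG
#'   stream derived from this seed, so adding artifacts never perturbs
#'   existing ones.
#'
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_tumor_ets_pos = 120,
                              n_tumor_ets_neg = 80,
                              n_normal = 40,
                              n_genes = 2000,
                              n_per_category = 26,
                              n_extra_both_up = 1,
                              effect_size = 1.5,
                              marker_shift = 4 * effect_size,
                              noise_sd = c(rnaseq = 0.9, microarray = 0.3),
                              frac_ar_bound = 0.08,
                              n_signature = 15,
                              signature_loading = 0.6,
                              hazard_coef = 1.0,
                              baseline_hazard = log(2) / 36,
                              censor_max = 48,
                              array_gain_mean = 0.35,
                              array_gain_sd = 0.08,
                              seed = 1L) {
  cfg <- list(
    n_tumor_ets_pos = n_tumor_ets_pos, n_tumor_ets_neg = n_tumor_ets_neg,
    n_normal = n_normal, n_genes = n_genes,
    n_per_category = n_per_category, n_extra_both_up = n_extra_both_up,
    effect_size = effect_size, marker_shift = marker_shift,
    noise_sd = noise_sd,
    frac_ar_bound = frac_ar_bound, n_signature = n_signature,
    signature_loading = signature_loading, hazard_coef = hazard_coef,
    baseline_hazard = baseline_hazard, censor_max = censor_max,
    array_gain_mean = array_gain_mean, array_gain_sd = array_gain_sd,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.categories <- c("ets_neg_up", "ets_neg_dn", "ets_pos_up", "ets_pos_dn", "both_up")
.markers <- c("ERG", "ETV1", "ETV4", "ETV5", "FLI1")

validate_sim_config <- function(cfg) {
  for (f in c("n_tumor_ets_pos", "n_tumor_ets_neg", "n_normal")) {
    if (!is_count(cfg[[f]], min = 2L)) abort("`", f, "` must be an integer >= 2")
  }
  if (!is_count(cfg$n_genes, min = length(.markers) + 1L)) {
    abort("`n_genes` must exceed the ", length(.markers), " marker genes")
  }
  if (!is_count(cfg$n_per_category, min = 0L)) abort("`n_per_category` must be >= 0")
  if (!is_count(cfg$n_extra_both_up, min = 0L)) abort("`n_extra_both_up` must be >= 0")
  n_planted <- 5L * cfg$n_per_category + cfg$n_extra_both_up
  if (n_planted > cfg$n_genes - length(.markers)) {
    abort("planted genes (", n_planted, ") exceed available non-marker genes")
  }
  if (!is_number(cfg$effect_size) || cfg$effect_size < 0) {
    abort("`effect_size` must be a non-negative number")
  }
  if (!is_number(cfg$marker_shift) || cfg$marker_shift < 0) {
    abort("`marker_shift` must be a non-negative number")
  }
  if (!all(c("rnaseq", "microarray") %in% names(cfg$noise_sd)) ||
    any(cfg$noise_sd[c("rnaseq", "microarray")] <= 0)) {
    abort("`noise_sd` must be positive and named 'rnaseq' and 'microarray'")
  }
  if (!is_number(cfg$frac_ar_bound) || cfg$frac_ar_bound <= 0 || cfg$frac_ar_bound >= 1) {
    abort("`frac_ar_bound` must lie in (0, 1)")
  }
  if (!is_count(cfg$n_signature, min = 0L)) abort("`n_signature` must be >= 0")
  if (!is_number(cfg$hazard_coef)) abort("`hazard_coef` must be a number")
  if (!is_number(cfg$baseline_hazard) || cfg$baseline_hazard <= 0) {
    abort("`baseline_hazard` must be positive")
  }
  if (!is_number(cfg$censor_max) || cfg$censor_max <= 0) {
    abort("`censor_max` must be positive")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes; per cohort ",
    x$n_tumor_ets_pos, " ETS+ / ", x$n_tumor_ets_neg, " ETS- tumors, ",
    x$n_normal, " normals; effect ", x$effect_size, "; seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# Sample table for one cohort: tumors first, then adjacent normals.
# ETS+ tumors get a driving ETS marker, ETS- tumors a non-ETS subtype label.
.sim_samples <- function(cfg, prefix) {
  n_pos <- cfg$n_tumor_ets_pos
  n_neg <- cfg$n_tumor_ets_neg
  drivers <- sample(c("ERG", "ETV1", "ETV4", "FLI1"),
    n_pos,
    replace = TRUE, prob = c(0.70, 0.15, 0.10, 0.05)
  )
  neg_subtypes <- sample(c("SPOP", "FOXA1", "IDH1", "other"),
    n_neg,
    replace = TRUE, prob = c(0.40, 0.25, 0.10, 0.25)
  )
  data.frame(
    sample_id = c(
      sprintf("%s_T%03d", prefix, seq_len(n_pos + n_neg)),
      sprintf("%s_N%03d", prefix, seq_len(cfg$n_normal))
    ),
    cohort = paste0("cohort_", prefix),
    tissue = c(rep("tumor", n_pos + n_neg), rep("adjacent_normal", cfg$n_normal)),
    ets_status = c(rep("ets_pos", n_pos), rep("ets_neg", n_neg), rep("unknown", cfg$n_normal)),
    subtype = c(drivers, neg_subtypes, rep("none", cfg$n_normal)),
    stringsAsFactors = FALSE
  )
}

# Per-gene, per-sample log2 shift implied by planted categories, ETS
# marker drivers, and the latent signature activity.
.sim_signal <- function(cfg, mu, truth, samples, activity, sig_genes) {
  n_g <- length(mu)
  n_s <- nrow(samples)
  shift <- matrix(0, n_g, n_s, dimnames = list(names(mu), samples$sample_id))
  is_pos <- samples$ets_status == "ets_pos"
  is_neg <- samples$ets_status == "ets_neg"
  e <- cfg$effect_size
  cat_of <- stats::setNames(truth$category, truth$gene_id)[names(mu)]
  shift[cat_of == "ets_neg_up", is_neg] <- e
  shift[cat_of == "ets_neg_dn", is_neg] <- -e
  shift[cat_of == "ets_pos_up", is_pos] <- e
  shift[cat_of == "ets_pos_dn", is_pos] <- -e
  # both_up genes rise in both strata but more strongly in ETS+ tumors,
  # so they are up versus normal in each stratum AND ETS-status
  # differential (as the real category-5 genes are).
  shift[cat_of == "both_up", is_neg] <- e
  shift[cat_of == "both_up", is_pos] <- 2 * e
  # driving ETS marker overexpression (outlier signal for subtyping)
  for (m in c("ERG", "ETV1", "ETV4", "FLI1")) {
    driven <- samples$subtype == m & samples$tissue == "tumor"
    if (any(driven)) shift[m, driven] <- shift[m, driven] + cfg$marker_shift
  }
  if (length(sig_genes)) {
    tum <- samples$tissue == "tumor"
    shift[sig_genes, tum] <- shift[sig_genes, tum] +
      cfg$signature_loading * matrix(activity[samples$sample_id[tum]],
        nrow = length(sig_genes), ncol = sum(tum), byrow = TRUE
      )
  }
  mu + shift
}

#' Simulate a two-cohort study with planted ETS-dependent AR programs
#'
#' Generates everything the pipeline consumes: an RNA-seq-style and a
#' microarray-style expression cohort drawn from the same gene-level
#' ground truth, sample annotation with planted ETS status and molecular
#' subtype, gene models on a single synthetic chromosome (TSS spaced
#' 120 kb apart so 25 kb windows never collide), AR binding sites within
#' 25 kb of the TSS for exactly the designated AR-target genes (and at
#' least 50 kb from every other TSS), a biochemical-recurrence table for
#' the RNA-seq cohort's tumors, and the ground-truth table itself.
#'
#' @param config A [simulation_config()].
#' @return An object of class `ets_cohort_sim`: a list with elements
#'   `expr` (list of `rnaseq` and `microarray` [expr_matrix()]),
#'   `annotation`, `gene_models`, `sites`, `survival`, `truth` (columns
#'   `gene_id`, `category`, `is_ar_target`, `is_decoy`, `is_signature`),
#'   `activity` (named latent pathway activity per tumor sample, both
#'   cohorts) and `config`.
#' @seealso [plant_decoys()], [make_gene_sets()], [write_cohort_sim()]
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  n_g <- cfg$n_genes
  gene_id <- c(.markers, sprintf("G%04d", seq_len(n_g - length(.markers))))

  # stream 1: planted category / AR-bound assignment and site geometry
  geom <- with_stream(cfg$seed, 1L, {
    pool <- setdiff(gene_id, .markers)
    n_cat <- rep(cfg$n_per_category, 5L)
    n_cat[5L] <- n_cat[5L] + cfg$n_extra_both_up
    planted <- sample(pool, sum(n_cat))
    category <- stats::setNames(rep("null", n_g), gene_id)
    category[planted] <- rep(.categories, times = n_cat)
    n_bound <- max(round(cfg$frac_ar_bound * n_g), length(planted))
    extra <- sample(setdiff(pool, planted), n_bound - length(planted))
    bound <- gene_id %in% c(planted, extra)
    sig_pool <- planted[category[planted] %in% c("ets_pos_up", "both_up")]
    sig_genes <- sample(sig_pool, min(cfg$n_signature, length(sig_pool)))
    tss <- 60000L + (seq_len(n_g) - 1L) * 120000L
    strand <- rep_len(c("+", "-"), n_g)
    sites <- do.call(rbind, lapply(which(bound), function(i) {
      srcs <- sample(c("chipseq_a", "chipseq_b", "chipseq_c"),
        1L + stats::rbinom(1L, 2L, 0.4)
      )
      off <- sample(c(-1L, 1L), length(srcs), replace = TRUE) *
        as.integer(round(stats::runif(length(srcs), 1500, 20000)))
      data.frame(
        chrom = "chrS", start = tss[i] + off - 200L,
        end = tss[i] + off + 200L, source = srcs,
        stringsAsFactors = FALSE
      )
    }))
    list(
      category = category, bound = bound, sig_genes = sig_genes,
      tss = tss, strand = strand, sites = sites
    )
  })

  truth <- data.frame(
    gene_id = gene_id,
    category = unname(geom$category),
    is_ar_target = geom$bound,
    is_decoy = FALSE,
    is_signature = gene_id %in% geom$sig_genes,
    stringsAsFactors = FALSE
  )
  gene_models <- data.frame(
    gene_id = gene_id, chrom = "chrS", tss = geom$tss,
    strand = geom$strand, stringsAsFactors = FALSE
  )

  # stream 2: baseline log2 abundance (normal-ish on the log2 scale)
  mu <- with_stream(cfg$seed, 2L, stats::setNames(stats::rnorm(n_g, 7, 1.5), gene_id))

  # streams 3 and 4: one cohort per platform, each with its own samples
  rnaseq <- with_stream(cfg$seed, 3L, {
    samples <- .sim_samples(cfg, "rnaseq")
    tum <- samples$sample_id[samples$tissue == "tumor"]
    activity <- stats::setNames(stats::rnorm(length(tum)), tum)
    signal <- .sim_signal(cfg, mu, truth, samples, activity, geom$sig_genes)
    vals <- signal + matrix(
      stats::rnorm(n_g * nrow(samples), 0, cfg$noise_sd[["rnaseq"]]),
      n_g, nrow(samples)
    )
    list(samples = samples, activity = activity, expr = expr_matrix(vals, "rnaseq"))
  })
  microarray <- with_stream(cfg$seed, 4L, {
    samples <- .sim_samples(cfg, "array")
    tum <- samples$sample_id[samples$tissue == "tumor"]
    activity <- stats::setNames(stats::rnorm(length(tum)), tum)
    gain <- pmax(stats::rnorm(n_g, cfg$array_gain_mean, cfg$array_gain_sd), 0.05)
    offset <- stats::rnorm(n_g, 0, 0.5)
    signal <- .sim_signal(cfg, mu, truth, samples, activity, geom$sig_genes)
    vals <- gain * signal + offset + matrix(
      stats::rnorm(n_g * nrow(samples), 0, cfg$noise_sd[["microarray"]]),
      n_g, nrow(samples)
    )
    list(samples = samples, activity = activity, expr = expr_matrix(vals, "microarray"))
  })

  annotation <- validate_annotation(rbind(rnaseq$samples, microarray$samples))
  activity <- c(rnaseq$activity, microarray$activity)

  # stream 5: biochemical recurrence for the RNA-seq cohort's tumors
  survival <- with_stream(cfg$seed, 5L, {
    simulate_survival(rnaseq$activity,
      hazard_coef = cfg$hazard_coef,
      baseline_hazard = cfg$baseline_hazard, censor_max = cfg$censor_max
    )
  })

  structure(
    list(
      expr = list(rnaseq = rnaseq$expr, microarray = microarray$expr),
      annotation = annotation, gene_models = gene_models,
      sites = geom$sites, survival = survival, truth = truth,
      activity = activity, config = cfg
    ),
    class = "ets_cohort_sim"
  )
}

#' @export
print.ets_cohort_sim <- function(x, ...) {
  cat("<ets_cohort_sim> ", x$config$n_genes, " genes, ",
    nrow(x$annotation), " samples across 2 cohorts; ",
    sum(x$truth$category != "null"), " planted category genes, ",
    sum(x$truth$is_ar_target), " AR-bound, ",
    sum(x$truth$is_decoy), " decoys\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate biochemical-recurrence times from per-sample scores
#'
#' Exponential event times with log hazard `hazard_coef * score` on top
#' of a baseline hazard, censored by an independent uniform time on
#' (0, `censor_max`). Uses the current RNG state.
#'
#' @param scores Named numeric vector of per-sample scores (e.g. latent
#'   pathway activity or a signature score).
#' @param hazard_coef Log hazard per unit score.
#' @param baseline_hazard Baseline exponential hazard per month.
#' @param censor_max Upper bound of the uniform censoring time (months).
#' @return A survival `data.frame` (`sample_id`, `time_months`, `event`).
#' @export
simulate_survival <- function(scores, hazard_coef,
                              baseline_hazard = log(2) / 36, censor_max = 48) {
  if (is.null(names(scores))) abort("`scores` must be named by sample id")
  rate <- baseline_hazard * exp(hazard_coef * scores)
  t_event <- stats::rexp(length(scores), rate)
  t_cens <- stats::runif(length(scores), 0, censor_max)
  validate_survival(data.frame(
    sample_id = names(scores),
    time_months = pmin(t_event, t_cens),
    event = t_event <= t_cens,
    stringsAsFactors = FALSE
  ))
}

#' Flag AR-bound tumor-equal-normal decoy genes
#'
#' Marks `n` AR-bound genes with no planted expression shift as decoys:
#' genes whose tumor and adjacent-normal distributions are identical by
#' construction. These are the genes the subtractive stage is expected
#' to place in its `removed` bucket. The expression matrices are not
#' altered — unshifted genes already satisfy the decoy property — only
#' the ground-truth table is updated.
#'
#' @param sim An `ets_cohort_sim`.
#' @param n Number of decoys to flag; must not exceed the available
#'   AR-bound unshifted (non-signature) genes.
#' @return The updated `ets_cohort_sim`.
#' @export
plant_decoys <- function(sim, n) {
  stopifnot(inherits(sim, "ets_cohort_sim"))
  if (!is_count(n, min = 0L)) abort("`n` must be a non-negative integer")
  if (n == 0L) {
    return(sim)
  }
  eligible <- sim$truth$gene_id[
    sim$truth$is_ar_target & sim$truth$category == "null" & !sim$truth$is_decoy
  ]
  if (length(eligible) < n) {
    abort(
      "only ", length(eligible),
      " AR-bound unshifted genes available for ", n, " decoys"
    )
  }
  chosen <- with_stream(sim$config$seed, 6L, sample(eligible, n))
  sim$truth$is_decoy[sim$truth$gene_id %in% chosen] <- TRUE
  sim
}

#' Gene-set collection matched to a simulated cohort
#'
#' Builds a GMT-style collection for the enrichment and signature stages
#' of a synthetic run: an androgen-response-like set (planted
#' up-regulated genes topped up with unshifted genes to the requested
#' size, emulating a 101-gene hallmark androgen-response list), the
#' planted signature pathway set, and a number of random unshifted sets.
#'
#' @param sim An `ets_cohort_sim`.
#' @param androgen_size Size of the androgen-response-like set.
#' @param n_random,random_size Number and size of random null sets.
#' @return A [gene_set_collection()].
#' @export
make_gene_sets <- function(sim, androgen_size = 101, n_random = 10, random_size = 50) {
  stopifnot(inherits(sim, "ets_cohort_sim"))
  truth <- sim$truth
  with_stream(sim$config$seed, 7L, {
    up <- truth$gene_id[truth$category %in% c("ets_pos_up", "ets_neg_up", "both_up")]
    nulls <- truth$gene_id[truth$category == "null"]
    if (length(up) >= androgen_size) {
      androgen <- sample(up, androgen_size)
    } else {
      androgen <- c(up, sample(nulls, androgen_size - length(up)))
    }
    sets <- list(ANDROGEN_RESPONSE_LIKE = androgen)
    sig <- truth$gene_id[truth$is_signature]
    if (length(sig) >= 2L) sets$SIGNATURE_PATHWAY <- sig
    for (i in seq_len(n_random)) {
      sets[[sprintf("RANDOM_%02d", i)]] <- sample(nulls, min(random_size, length(nulls)))
    }
    gene_set_collection("synthetic_sets", sets)
  })
}

#' Write every artifact of a simulated cohort to a directory
#'
#' Emits the on-disk form of each generated object using the package's
#' standard formats: per-platform expression TSVs, annotation TSV, gene
#' models TSV, AR binding sites BED, survival TSV and the ground-truth
#' table (`ground_truth.tsv`).
#'
#' @param sim An `ets_cohort_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "ets_cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr$rnaseq, file.path(dir, "expr_rnaseq.tsv"))
  write_expression(sim$expr$microarray, file.path(dir, "expr_microarray.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_gene_models(sim$gene_models, file.path(dir, "gene_models.tsv"))
  write_bed(sim$sites, file.path(dir, "ar_sites.bed"))
  write_survival(sim$survival, file.path(dir, "survival.tsv"))
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
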