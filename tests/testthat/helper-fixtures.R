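# Shared fixture builders. All fixtures are generated in code; tests fix
# their own seeds.

# Tiny expression matrix with explicit values.
tiny_expr <- function(values, genes, samples, platform = "rnaseq") {
  expr_matrix(
    matrix(values, length(genes), length(samples),
      dimnames = list(genes, samples), byrow = TRUE
    ),
    platform
  )
}

# A small planted two-group matrix: `n_shift` genes shifted by `delta`
# in group 1. Returns the expr_matrix plus a tumor-only annotation with
# ets_pos = group 1.
two_group_expr <- function(n_genes = 50, n1 = 10, n2 = 10, n_shift = 5,
                           delta = 2, sd = 1, seed = 1, platform = "rnaseq") {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- c(sprintf("p%02d", seq_len(n1)), sprintf("q%02d", seq_len(n2)))
  vals <- matrix(rnorm(n_genes * (n1 + n2), 5, sd), n_genes,
    dimnames = list(genes, samples)
  )
  vals[seq_len(n_shift), seq_len(n1)] <- vals[seq_len(n_shift), seq_len(n1)] + delta
  annot <- data.frame(
    sample_id = samples, cohort = "c1", tissue = "tumor",
    ets_status = rep(c("ets_pos", "ets_neg"), c(n1, n2)),
    subtype = rep(c("ERG", "SPOP"), c(n1, n2)),
    stringsAsFactors = FALSE
  )
  list(expr = expr_matrix(vals, platform), annot = annot, shifted = genes[seq_len(n_shift)])
}

# Default small simulation for module tests (fast, clearly separated).
small_sim <- function(seed = 7, ...) {
  args <- list(
    n_tumor_ets_pos = 30, n_tumor_ets_neg = 30, n_normal = 15,
    n_genes = 400, n_per_category = 8, n_extra_both_up = 0,
    frac_ar_bound = 0.15, seed = seed
  )
  args[names(list(...))] <- list(...)
  simulate_cohort(do.call(simulation_config, args))
}
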