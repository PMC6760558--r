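# etsar

**ETS-stratified androgen receptor target discovery in prostate cancer
transcriptomes.**

Roughly half of prostate cancers carry a gene fusion that places an
ETS-family transcription factor (most often ERG, via TMPRSS2-ERG) under
androgen control. `etsar` implements, as tested reusable R functions, a
pipeline for asking whether the androgen receptor (AR) drives *different*
transcriptional programs in ETS-fusion-positive (ETS+) and
fusion-negative (ETS−) tumors:

1. **ETS subtyping** — call ETS+/ETS− status per tumor from outlier
   expression of the marker panel (ERG, ETV1, ETV4, ETV5, FLI1):
   a sample is ETS+ if any marker exceeds `median + k·MAD` of a
   reference sample set (default `k = 3`).
2. **Differential expression** — per gene, a two-sided Mann–Whitney U
   test between ETS+ and ETS− tumors, Benjamini–Hochberg adjustment,
   and a dual significance rule: `q < 0.05` **and**
   `|log2 FC| > fc_min`, with `fc_min = 0.585` on the RNA-seq scale and
   `0.05` on the compressed microarray (SCAN-style) scale.
3. **Cross-cohort intersection** — genes differential in *both* cohorts
   with the *same* direction, plus the Pearson correlation of their
   log2 fold changes across platforms.
4. **Direct AR target annotation** — a gene is a direct AR target if an
   AR ChIP-seq binding site lies within 25 kb of its TSS (symmetric by
   default; a strand-aware downstream-only mode is provided), with
   multi-study support counting.
5. **Subtractive categorization** — compare each tumor stratum to
   adjacent normal tissue; AR targets not different from normal in
   either stratum are *removed*, and the survivors fall into five
   ETS-dependent categories: ETS− Up, ETS− Dn, ETS+ Up, ETS+ Dn, and
   ETS−/ETS+ Up.
6. **Over-representation analysis** — upper-tail hypergeometric tests
   of the up-regulated lists against GMT gene-set collections.
7. **Signature scoring** — summarize a pathway gene set per sample by
   its first principal component; certify coherence against a
   random-gene-set null (PC1 % variance and PC1/PC2 ratio percentiles).
8. **Biochemical recurrence** — median-split Kaplan–Meier curves and
   the log-rank test of the signature score within each ETS stratum.

Because the cohorts this kind of analysis runs on are controlled-access,
the package ships a first-class **synthetic study generator**
(`simulate_cohort()`) that emulates the full design — two platforms with
an affine gain distortion, planted category genes, fusion-marker
outliers, AR binding-site geometry, tumor-equal-normal decoy genes, and
recurrence times driven by a planted pathway activity — so every stage
can be validated against a known ground truth.

It is aimed at computational biologists who want either the complete
funnel (`run_all()`) or the individual stages (`run_de()`,
`annotate_targets()`, `assign_categories()`, `pc1_score()`,
`bcr_analysis()`, ...) as building blocks on their own data, read from
plain TSV / BED / GMT files.

## Worked example

```r
library(etsar)

config <- pipeline_config(
  sim        = simulation_config(seed = 1),  # 2 cohorts, 2000 genes, 131 planted AR targets
  n_decoys   = 29,                           # AR-bound genes identical to normal
  ets_source = "call",                       # re-derive ETS status from marker outliers
  n_null     = 1000                          # random gene sets for the signature null
)
res <- run_all(config, "results/demo")
print(res)
```

```
<ets_pipeline_result>
  DE: 133 rnaseq (6.7%), 140 microarray (7.0%) of 2000 genes
  overlap: 132 (80 up ETS+, 52 up ETS-); log2FC r = 0.967
  AR targets: 160; in overlap: 131; removed vs normal: 0; categorized: 131
  signature PC1: 55.0% var (null pctl 100.00); log-rank p ETS+ 0.000898, ETS- 0.000254
```

Reading the funnel: about 7% of genes are differential by ETS status on
each platform; 132 genes replicate across platforms with concordant
direction and strongly correlated fold changes (r = 0.97); 131 of the
160 direct AR targets survive the intersection and the subtraction
against adjacent normal, recovering the planted five-category program.
The planted pathway signature is summarized per sample by PC1:

```r
print(res$signature)
#> <signature_score> 'SIGNATURE_PATHWAY': PC1 explains 55.0% of variance
#> (better than 100.00% of 1000 random models); PC1/PC2 = 11.22 (better than 100.00%)

print(res$bcr$ets_pos)
#> <bcr_result> high n = 60, low n = 60; log-rank p = 0.000898
```

so the signature is far more coherent than size-matched random gene
sets, and splitting ETS+ tumors at the median score separates their
biochemical-recurrence curves (log-rank p ≈ 9e-4). Stage tables
(`de_*.tsv`, `overlap.tsv`, `targets.tsv`, `categories.tsv`,
`enrichment_*.tsv`, `scores_*.tsv`, `km_*.tsv`), a funnel `summary.tsv`
and a `run_manifest.yaml` recording every threshold and seed are written
to the output directory.

The methods vignette (`vignettes/ets-ar-programs.Rmd`) documents the
models, default parameters, generator design and known limitations.

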