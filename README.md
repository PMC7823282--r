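# consensusDEG

Method-agnostic consensus reference standards for evaluating
single-subject differential expression.

## The problem

Single-subject (N-of-1) transcriptome designs compare one RNA-seq sample
per condition — a patient as their own control — so there are no
replicates from which to estimate dispersion, and no biological gold
standard against which to judge a caller's differentially expressed genes
(DEGs). The common workaround, scoring a method against a reference
standard built *by that same method* on replicated data, is an
*isomorphic* evaluation: it replicates the method's own systematic
artifacts and is anticonservative by construction. Different callers also
disagree massively at loose thresholds, because their distributional
assumptions (binomial, negative binomial, non-parametric) handle
low-count, low-effect genes differently.

`consensusDEG` builds *heteromorphic*, method-agnostic reference
standards from replicated isogenic data:

1. **Filter.** Genes enter the analysis universe through a low-expression
   cutoff (minimum average raw count across all samples) and are
   stratified by fold-change windows. The per-gene fold change is
   `FC_k = A_k / B_k` (condition means); down-regulated genes are mapped
   to their reciprocal so windows are symmetric about 1 on the *oriented*
   scale `max(FC, 1/FC)`.
2. **Concord.** Within each (cutoff, window) cell of the grid, every
   registered caller's significant set (Benjamini–Hochberg within the
   filtered universe, `padj < alpha`) is compared pairwise by the Jaccard
   index `J(M, N) = |M ∩ N| / |M ∪ N|`, and the cell is summarised by the
   median over pairs.
3. **Optimize.** The grid (default 5 windows × 6 cutoffs = 30 cells) is
   searched cutoffs-ascending, windows-ascending, stopping at the first
   cell whose median concordance reaches the target (default 0.75) — the
   least destructive filter that makes the methods agree.
4. **Consense and evaluate.** At that region, positives are the
   intersection (or strict majority vote) of the callers' sets — always
   *excluding* the method under evaluation. Hold-out 1-vs-1 sample pairs,
   disjoint from the reference samples, emulate the single-subject
   setting; the evaluated caller's predictions on each pair are scored by
   precision and recall against the consensus standard and averaged.

The package ships four built-in two-condition callers spanning the usual
distributional families (exact conditional test on pooled counts,
negative-binomial Wald with trend-shrunk dispersion, exact rank-sum,
delta-method z-test on log ratios), an adapter for externally computed
DEG tables (`gene_id / log2fc / pvalue / padj` TSV), and a
negative-binomial simulator with planted fold changes for calibration and
recovery studies.

## Worked example

```r
library(consensusDEG)

# a replicated isogenic study: 2000 genes, 7 replicates per condition,
# ~12% of genes with planted fold changes across the default windows
sim <- simulate_two_condition_counts(sim_config(
  n_genes = 2000, n_replicates = 7, deg_fraction = 0.12, seed = 101))
sim$counts
#> count_matrix: 2000 genes x 14 samples (A=7, B=7)

res <- optimize_concordance(sim$counts, deg_methods(), target = 0.75)
res
#> optimizer_result: attained target 0.75 at cutoff 50, FC window [1.5, Inf) (median 0.751)

plan <- make_holdout_plan(sim$counts, n_reference_per_condition = 4,
                          n_pairs = 3, seed = 202)
rep <- evaluate_prediction_method(sim$counts, plan, "pooled_exact",
  rs_rule = "majority",
  region = list(cutoff = res$cutoff, fc_lower = res$fc_lower,
                fc_upper = res$fc_upper))
rep
#> evaluation_report: pooled_exact predicted vs majority-of-{nb_wald, rank_sum, zlogfc} standard
#>   region: cutoff 50, FC [1.5, Inf)
#>   average precision 0.085, average recall 0.864 over 3 pair(s)
```

Reading the output: at the concordance-optimal region (genes averaging
at least 50 counts, oriented fold change at least 1.5) the four callers'
median pairwise Jaccard index is 0.751 — against 0 in the unfiltered
low-effect cell. The hold-out evaluation then scores the pooled exact
caller, run on three independent single-subject pairs, against the
majority-vote consensus of the *other three* callers built on the four
reference replicates per condition: it recovers 86% of the consensus
positives, at low precision — the pooled test, which cannot see
biological replicate variability, over-calls in a two-conditions-without-
replicates design. That asymmetry is exactly what the framework is built
to expose.

External tools plug in without code: `read_deg_table()` +
`adapt_external_degs()` treat a tool's own adjusted p-values as
authoritative, and the same grid, consensus and evaluation machinery
applies.

A command-line wrapper with `simulate`, `optimize`, `build-rs`,
`evaluate` and `report` subcommands is installed at
`inst/cli/consensusDEG` (see `cli_main()`); every run writes a frozen
config snapshot next to its outputs.

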