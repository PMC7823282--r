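---
title: "Building method-agnostic reference standards for single-subject differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building method-agnostic reference standards for single-subject differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusDEG)
```

## Motivation and model

A single-subject (N-of-1) transcriptome study measures one RNA-seq
sample per condition in one individual. Without replicates there is no
within-condition dispersion estimate, and without a gold standard there
is no direct way to judge which of the many two-condition DEG callers to
trust. Evaluations that build a reference standard with the *same*
analytical method that generates the predictions (isomorphic
evaluations) systematically confirm that method's artifacts; the remedy
is a *heteromorphic* standard built by a consensus of other methods.

The catch is that DEG callers disagree most exactly where single-subject
signal is weakest: low expression and small effect sizes. This package
therefore treats the reference standard as the outcome of an
optimization: find the mildest joint filter — a minimum average
expression and a fold-change window — under which independent callers
agree well enough that their consensus is meaningful.

Formally, for gene $k$ with condition means $A_k$ and $B_k$,

$$\mathrm{FC}_k = A_k / B_k, \qquad
  \mathrm{FC}^{\mathrm{or}}_k = \max(\mathrm{FC}_k, 1/\mathrm{FC}_k),$$

so up- and down-regulation are not distinguished when windowing: a gene
at $\mathrm{FC} = 1/1.25$ lands in the same window as one at 1.25.
Agreement between two callers' significant sets $M, N$ within a region
is the Jaccard index $J = |M \cap N| / |M \cup N|$, a region is
summarised by the median $J$ over all unordered method pairs, and the
search returns the first region (cutoffs ascending, then windows
ascending by lower bound) whose median reaches the target.

## The pipeline and its parameters

| parameter | default | meaning |
|---|---|---|
| `expression_cutoffs` | 0, 5, 10, 20, 30, 50 | minimum average raw count across *all* samples (counts) |
| `fc_windows` | [1,1.1), [1.1,1.2), [1.2,1.3), [1.3,1.5), [1.5,∞) | oriented-scale windows, half-open |
| `alpha` | 0.05 | significance level on BH-adjusted p-values (0.001 preset available) |
| `target` | 0.75 | median pairwise Jaccard to attain |
| `pseudocount` | 0.5 | added to both means only when either is zero |
| `scaling` | total_count | each sample scaled to the mean library size before means/ranks |
| `n_reference`, `n_pairs` | 4, 3 | hold-out split per condition |

Several choices here were genuinely open and are worth recording:

* **Half-open windows.** Printed bracket notations for fold-change
  ranges are ambiguous at the boundaries; `[lower, upper)` guarantees
  the windows partition the oriented axis, and an infinite upper bound
  additionally captures infinite oriented fold changes (one condition
  mean exactly zero at pseudocount 0).
* **Test once per cutoff, stratify by window.** DEG calling and the BH
  adjustment happen once on each cutoff's full filtered universe —
  prefiltering is a power gain precisely because the correction runs
  after it — and the fold-change windows then *stratify* the significant
  sets rather than triggering re-testing. (`retest` semantics would
  change the multiplicity universe per window; the stratify reading
  matches a workflow that organises one set of results by effect size.)
* **Fold changes from scaled means; cutoffs from raw means.** The
  expression cutoff is defined on raw average counts (what "average
  expression under the threshold" means operationally), while condition
  means entering fold changes are library-size scaled by default. The
  two callers that model library sizes explicitly (pooled exact, NB
  Wald) always consume raw counts plus offsets.
* **Traversal order and ties.** Cutoffs outer-ascending, windows
  inner-ascending: the first hit is the least destructive combination,
  i.e. the smallest thresholds attaining the target, and ties are
  resolved by traversal order alone (first-hit semantics).
* **Empty sets.** A pair of empty significant sets has no defined
  Jaccard index (`NA`, rendered as blank cells in the heatmap export);
  one empty set against a non-empty one is a defined 0. Undefined
  medians never satisfy the target: an all-empty region carries no
  evidence of concordance. Whether all-empty pairs should instead count
  as zeros is not determinable from first principles; the defined-pairs
  rule is a documented convention, not an inference.
* **Strict majority.** With an even number of contributing methods,
  "simple majority" needs a tie rule; `majority` means strictly more
  than half (3 of 4), the conservative reading. Intersection ⊆ majority
  ⊆ union always holds.
* **Consensus universe.** A reference standard's negatives are the
  remaining genes of its region's *expression-filtered* universe, not of
  the full transcriptome; the size report records both counts.

## Built-in callers and their calibration

The four built-in callers are deliberately heterogeneous stand-ins
spanning the distributional families found in production RNA-seq tools;
they are not reimplementations of any specific tool. Results from real
tools enter through `read_deg_table()` / `adapt_external_degs()`, whose
adjusted p-values are taken as authoritative (no re-adjustment).

* `pooled_exact` — pools counts per condition and applies the exact
  conditional test to each gene's 2×2 table (gene vs rest of library),
  two-sided by summing all table probabilities no larger than the
  observed one. Valid with a single sample per condition; in replicated
  overdispersed data it is anticonservative *by design*, which is
  exactly the behaviour a consensus framework must be robust to.
* `nb_wald` — per-gene negative binomial with library-size offsets and
  a method-of-moments dispersion shrunk 50/50 toward a lowess trend of
  dispersion on log mean. The trend is fitted on *unclipped* moment
  estimates (clipping negative values first would bias every shrunk
  estimate upward). The Wald statistic is referred to a t distribution
  with $2(n_A + n_B - 2)$ degrees of freedom: the residual df plus an
  equal prior contribution, reflecting that half the dispersion weight
  comes from the genome-wide trend. With an externally fixed dispersion
  (the 1-vs-1 setting) there is no estimation noise and the normal
  reference applies.
* `rank_sum` — exact two-sample rank-sum test on scaled counts
  (`pwilcox`), falling back to the tie-corrected normal approximation
  when counts tie; requires ≥ 3 replicates per condition and is refused
  for 1-vs-1 prediction.
* `zlogfc` — z-test on the log ratio of scaled condition means with a
  delta-method variance $\mathrm{Var}(\log \bar{x}) \approx
  1/(n\bar{x}) + \phi/n$ from a Poisson-plus-dispersion model, using the
  same moderated-t reference as `nb_wald` when $\phi$ is estimated.

Calibration was designed around each caller's *own* null — data
generated under its distributional assumptions — because, e.g., pooling
across overdispersed replicates inflates the pooled test for reasons
that are a finding of the framework, not a defect of the test. Two
discreteness facts matter and were computed before any test was run:
the exact rank-sum test's attainable two-sided size at $\alpha = 0.05$
is 0 for 3v3, 0.032 for 5v5, 0.038 for 7v7 and 0.045 for 12v12, so its
calibration scenario uses 12 replicates per condition; and the same
p-value floor ($2/70$ at 4v4) means an intersection consensus that
includes the rank caller is structurally empty at 4 reference
replicates after BH — which is why the hold-out examples default to the
majority rule, whose robustness to a single method's false negatives is
the point of voting.

## What the simulator emulates — and what it does not

`simulate_two_condition_counts()` draws negative-binomial counts for an
isogenic two-condition design: log-normal baseline means (default
meanlog $\log 60$, sdlog 1.5, so the default cutoffs 5–50 remove
meaningful but not degenerate fractions of genes), constant dispersion
0.05 (cell-line-like biological variability; a mean-dependent `trend`
option exists for stress tests), 7 replicates per condition, mild
log-normal library-size variation (sdlog 0.15), and a planted 12% DEG
fraction whose oriented fold changes are drawn from the five standard
windows with weights 85:175:700:1100:365 — an empirical-looking
effect-size spectrum in which moderate effects dominate. Directions are
random and the planted ratio multiplies one condition's mean, so the
true A/B ratio equals the signed fold change. Seeds are mandatory and
the generator restores the caller's RNG stream.

It does **not** emulate: gene–gene correlation, batch or GC effects,
read-level noise, isoform structure, or heavy-tailed outlier samples.
Passing recovery tests on this generator therefore shows the machinery
is correct and the phenomena (concordance rising with both filters;
consensus precision at or above every contributing caller's) are
reproduced under clean negative-binomial conditions — not that any
particular concordance value will be observed on real data, where the
optimal region is dataset-specific.

## Numerical choices and degenerate inputs

* Counts must be integral within $10^{-6}$ (preprocessed public
  matrices are often near-integer) and are rounded on load.
* Zero denominators: the pseudocount is applied to *both* means only
  when either is zero, preserving the ratio's ranking elsewhere; at
  pseudocount 0 a both-zero gene has an undefined fold change and joins
  no window.
* All-zero sample columns get a unit scale factor rather than a 0/0.
* The NB group fit solves the offset log-mean score equation by a
  damped Newton iteration vectorised across genes (steps clamped to
  ±4, 50 iterations, tolerance $10^{-12}$); empty groups use a
  half-count continuity value. Wald variances use expected information.
* An empty filtered universe yields all-undefined concordance cells,
  which can never satisfy a target; an optimizer run that attains
  nothing reports `attained = FALSE` with its message rather than a
  region.
* Hold-out prediction pairs re-apply the region's filters on the pair
  itself by default (`filter_predictions = FALSE` scores the raw
  1-vs-1 calls instead — both readings of "compare at the optimal
  region" are one flag apart).

## Problem sizes

The shipped tests and the acceptance script run, by choice, at desk
scale: 2000-gene calibration and optimizer-equivalence studies, a
5000-gene × 7-replicate recovery study, and 300–800-gene integration
fixtures. These sizes already exhibit every phenomenon the package
asserts (the discreteness analyses above are sample-size, not
gene-count, effects); the machinery itself is routinely run at 20k
genes.

## Known limitations

* The built-in callers are calibrated stand-ins; conclusions about any
  *specific* production tool require routing that tool's tables through
  the adapter.
* The grid search optimises within the user's grid only; no
  extrapolation or self-tuning beyond it.
* Consensus rules are unweighted; no probabilistic or rank-aggregation
  ensembles.
* Precision/recall against a consensus standard measures agreement with
  the consensus, not biological truth; on simulated data
  `truth_metrics()` closes that gap, on real data nothing can.
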