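---
title: "Scoring tumor-suppressor disruption from variants, copy number and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tumor-suppressor disruption from variants, copy number and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bap1tools)
```

## The problem

Loss of a tumor suppressor such as *BAP1* can arise through several
mechanisms — point mutations, long insertions/deletions that individual
callers miss, and copy-number loss of the surrounding chromosomal segment.
Each mechanism is observed through a different assay, and no single variant
caller sees all of the mutations. `bap1tools` implements the downstream half
of such an analysis: it consumes caller-level MAF tables, gene-level integer
copy numbers, SEG segments and a counts matrix, and produces per-sample
alteration categories, a direction-weighted expression activity score, and a
binary mutant-like / wildtype-like classification.

## Variant merging and filtering

Calls from any number of callers are deduplicated on the key
`(sample, chrom, start, ref, alt)`. The original pipelines reconcile
read-support metrics in unspecified ways, so the package makes the rule
explicit: a configurable **caller-priority list** (defaulting to input
order) decides which caller's `t_alt_count`, `t_depth` and classification
become the consensus, while all contributing caller labels are retained in
a provenance column. A variant is considered to have passed caller-level QC
when *at least one* caller flagged it `PASS`, because each caller's filter
field is meaningful only for its own call.

Read-support filtering retains variants with

* VAF = `t_alt_count / t_depth` ≥ 0.2 (evaluated on the consensus values;
  per-caller pre-merge evaluation is possible by filtering each table before
  merging),
* `t_alt_count` ≥ 2, and
* no entry on a machine-readable **exclusion list**. Manual inspection of
  read alignments in a genome browser is inherently irreproducible, so the
  package models it as an explicit input: a reviewer's rejections become a
  table that is versioned with the analysis.

Indel length is the absolute allele-length difference with `"-"` counting
as length zero; "long" indels default to ≥ 40 bp. Callset comparison
(`compare_callsets()`) exposes *all* set sizes (shared / gained / lost,
total and somatic) rather than one canonical percent increase, because the
baseline definition (all prior calls vs quality-filtered prior calls)
changes the headline number; the somatic percent increase is reported from
the somatic counts. A window-matching mode (same sample and chromosome,
positions within *w* bp, nearest wins, ties to the lower coordinate)
handles near-matches such as cross-genome-build coordinate shifts.

## Copy number

A sample has gene-level loss when its integer copy number is `< 2`; depth
is "single" (1) or "deep" (0). Loss-segment widths use the segment
overlapping the gene locus; when several overlap, the one with maximal
overlap wins, ties going to the wider segment (the data do not determine a
unique choice; this rule is deterministic and favors the segment that best
explains the locus). Widths are summarized as median and IQR with
**type-7 (linear interpolation) quantiles**, the default of the scientific
stacks these summaries are usually produced with. No focal-vs-arm
categorical cutoff is imposed — raw widths are reported.

Alteration categories are pure set arithmetic: `MutPlusCN` (mutation and
loss), `MutOnly`, `CNOnly`, `Unaltered`; counts always conserve the sample
universe.

## The activity score

The only normalization defined for any score in this framework is
*z*-scores of median-centered log2 counts, so it is applied uniformly:

  z[g, s] = (log2(x[g, s] + 1) − median_s log2(x[g, ·] + 1)) / sd_s

with the sample (n−1) standard deviation and pseudocount 1 (both choices
are conventions; a sensitivity check with population sd changes scores by a
factor √(n/(n−1)) per gene and no classification in our simulations).
Constant genes get an all-zero row and a flag rather than NaNs.

The signature is built from a differential-expression table (mutant vs
unaltered): genes with adjusted p < 0.05 enter, **up**-in-mutant genes with
weight −1 and **down** genes with weight +1, so that low scores mean low
activity of the disrupted gene. A fold-change cutoff is exposed
(`min_abs_lfc`) but defaults to 0, since the reference analysis used the
|log2FC| ≥ 1.5 boundary only as a plot annotation. The weighted score is
the signed sum (optionally mean) of z-scores over signature genes.

The package's internal DE stage (`simple_de()`) is a deliberately simple
substitute for a negative-binomial GLM pipeline: per-gene two-sided
Mann–Whitney tests with continuity correction on log2 CPM, BH adjustment,
and a mean log2-CPM difference as the fold change. It performs **no
covariate adjustment** (tumor purity, histological subtype); externally
produced DE tables carrying such adjustments are accepted anywhere a DE
table is consumed.

`rank_score()` is a simplified directed mean-rank statistic in the spirit
of rank-based single-sample scoring: per sample all genes are ranked, ranks
are normalized to (0, 1), and the score is mean(rank of down-genes) −
mean(rank of up-genes). It is *not* a re-implementation of any published
rank-score package; the contract is concordance with the weighted score
(squared correlation ≥ 0.8 on synthetic cohorts), not equality.

## Classification

Scores are classified by a univariate two-component Gaussian mixture fitted
by EM, with BIC choosing between equal- and unequal-variance models (the
binary mutant-like / wildtype-like question fixes the number of components
at two). Initialization is a median split plus `n_init` random restarts
under a caller-supplied seed, keeping the best log-likelihood — determinism
with robustness to local optima. The mutant-like component is the one with
the lower mean. The threshold is the score between the means where the
posterior crosses 0.5; a sample exactly at posterior 0.5 is called
wildtype-like (the conservative direction). A frozen fit can be serialized
to JSON and applied to new cohorts (`apply_external_threshold()`); whether
to refit per cohort or reuse a reference fit is a scientific choice the
package leaves to the analyst — both routes are first-class.

Numerical safeguards: variances are floored at 1e−8 of the data variance to
keep EM from collapsing onto a point; fits that stop on the iteration cap
are flagged `converged = FALSE`; degenerate (constant) inputs error rather
than returning a meaningless fit.

## Statistics toolbox

`mann_whitney_cc()` (normal approximation, tie correction, continuity
correction; exact enumeration below 15 total observations, used as the test
oracle), `fisher_exact_2x2()` (two-sided by the probability method — all
tables with probability ≤ the observed are summed), `spearman()` (average
ranks, t-approximation p), `adjusted_r2()` pinned to the Wherry variant
1 − (1 − r²)(n − 1)/(n − k − 1) (the literature has several "Wherry"
formulas; this is the one this package means), and `p_adjust()`
(Bonferroni and BH step-up with monotonicity). All of these are implemented
in-package and tested against independent oracles, including base R.

## What the synthetic data does and does not establish

The generators emit every input type with ground truth:

* `gen_expression_cohort()` — NB counts (variance μ + αμ², α = 0.1 by
  default, the standard bulk RNA-seq regime), log-normal gene baselines
  (log2 mean ~ N(5, 2)), 200 samples, 15% mutant, 100 signature genes
  shifted ±1 log2 unit in mutants. These defaults are the stated world of
  the validation suite and are not tuned.
* `gen_variant_truth()` / `gen_caller_tables()` — true VAFs Beta(8, 8)
  (mean 0.5, echoing a clonal-heterozygous cohort where the observed mean
  VAF was ≈ 0.46 ± 0.21), Poisson depths around 60×, per-caller
  sensitivities/false-positive rates, long indels emitted only by
  indel-capable callers, read support jittered (Poisson depth, binomial alt
  count floored at one read).
* `gen_cn_tables()` — single-copy loss with 1% deep loss, loss-segment
  widths from a focal (log-uniform 0.1–30 Mb) / arm-level (60–90 Mb)
  mixture.
* `gen_timecourse()` — latent times on a uniform grid, signature genes
  whose log2-means move linearly with time (up-genes falling, so the
  activity score rises with differentiation), Gaussian log-mean noise
  (0.3), NB counts.

A green suite on these data establishes that the *pipeline machinery*
recovers planted truth: scores separate classes (AUROC ≥ 0.95), the mixture
reproduces truth labels (≥ 95%), rank and weighted scores are concordant
(r² ≥ 0.8), and the timecourse gradient is recovered (Spearman ≥ 0.9,
adjusted r² ≥ 0.7). It does **not** establish anything about real cohorts:
the generators model no batch effects, no tumor purity, no subtype
structure, no library-size extremes, no single-cell dropout beyond NB
noise, and no correlated co-deletion of neighboring genes. Cohort-level
headline counts from the reference analysis (e.g. retained-variant totals)
depend on controlled-access inputs and are therefore not reproduced by the
test suite.

In `simulate all`, the different generators receive distinct sub-seeds
derived from the user seed; reusing one seed verbatim would correlate their
sampling prefixes (the mutant samples would always be a subset of the
CN-loss samples). Each generator remains a pure function of its own seed.

## Known limitations

* Allele normalization (left-alignment, MNV decomposition) is assumed done
  upstream; merging is exact-key.
* The internal DE substitute is rank-based and unadjusted; with strong
  confounding it will select a biased signature — supply an external DE
  table in that situation.
* The mixture is univariate and two-component by construction; score
  distributions with more structure will be forced into two classes.
* `loss_segment_widths()` reports the single best-overlapping segment per
  sample; fragmented segmentations are summarized by that one segment.

## End-to-end example

```{r, eval = FALSE}
sim <- file.path(tempdir(), "sim"); run <- file.path(tempdir(), "run")
cli_main(c("simulate", "--what", "all", "--seed", "7", "--out", sim))
cli_main(c("run",
           "--maf", file.path(sim, "caller1.maf"),
           "--maf", file.path(sim, "caller2.maf"),
           "--gene-cn", file.path(sim, "gene_cn.tsv"),
           "--seg", file.path(sim, "segments.seg"),
           "--counts", file.path(sim, "counts.tsv"),
           "--out", run, "--seed", "11"))
jsonlite::read_json(file.path(run, "manifest.json"))$stage_counts
```
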