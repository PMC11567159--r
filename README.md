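# bap1tools

Integrated characterization of tumor-suppressor disruption — *BAP1* by
default — from multi-omic cohort data, for cancer genomics analysts working
at the post-caller level. Variants in a gene like *BAP1* are systematically
under-detected by any single caller, and much of the biological loss comes
from copy-number deletion rather than mutation at all; naive analyses
therefore mislabel altered samples and dilute downstream expression
signatures. `bap1tools` provides the downstream pipeline:

1. **Multi-caller variant integration** — merge MAF-level calls from any
   number of callers/pipelines into consensus records with caller
   provenance, filter by read support (VAF ≥ 0.2, alternate reads ≥ 2,
   PASS in ≥ 1 caller, machine-readable exclusion list in place of manual
   review), flag long indels (≥ 40 bp), and compare callsets against a
   baseline.
2. **Copy-number integration** — gene-level loss calls (integer copy
   number < 2), loss-segment width summaries (median/IQR, type-7
   quantiles), and disjoint per-sample alteration categories
   (`MutOnly` / `CNOnly` / `MutPlusCN` / `Unaltered`).
3. **Activity scoring** — from a differential-expression table
   (mutant vs unaltered), build a direction-weighted signature and score
   each sample as

   `score(s) = Σ_g w_g · z_gs`,  `w_g = −1` for genes up in mutants,
   `+1` for genes down, `z_gs` the z-score of median-centered
   log2(count + 1),

   so low scores mean low gene activity. A rank-based score and a
   gene-set (mean-z) score are included.
4. **Classification** — a two-component Gaussian mixture (EM, BIC choice
   between equal/unequal variance) splits scores into **mutant-like**
   (lower-mean component) and **wildtype-like**, with an explicit
   posterior-0.5 threshold that can be frozen and applied to new cohorts.
5. **Synthetic data** — seeded negative-binomial generators for every input
   type with ground truth, so the entire chain is testable offline.

## Worked example

```r
library(bap1tools)

cohort <- gen_expression_cohort(seed = 7)   # 200 samples, 15% mutant
mut    <- cohort$truth$true_status == "mutant"

de  <- simple_de(cohort$counts, ifelse(mut, "mutant", "unaltered"))
sig <- build_signature(de)                  # padj < 0.05
nrow(sig)
#> [1] 106                                  # 54 up / 52 down in mutants

scores <- weighted_score(normalize_counts(cohort$counts), sig)
fit    <- fit_score_mixture(scores, seed = 17)
fit
#> 2-component Gaussian mixture (equal variance), n = 200
#>   means -130.8 / 16.45, sds 8.561 / 8.561, weights 0.150 / 0.850
#>   logLik -797.774, BIC 1616.742, threshold -58.03, converged: TRUE

cls <- classify_scores(scores, fit, truth = cohort$truth$true_status)
cls$summary$agreement
#> [1] 1

mann_whitney_cc(scores$score[mut], scores$score[!mut])
#> Mann-Whitney U (normal approx., cc): statistic = 0, p = 2.71087e-18 (n = 30+170)
```

The fit found a small low-score component (weight 0.150 — exactly the
planted mutant fraction) far below the bulk of the cohort; every sample
landed on the correct side of the −58.03 threshold, and the
mutant-vs-wildtype score difference is maximal (U = 0: every mutant scores
below every wildtype sample).

A one-shot driver runs the whole chain from files and writes a manifest
with per-stage counts:

```r
sim <- tempfile(); run <- tempfile()
cli_main(c("simulate", "--what", "all", "--seed", "7", "--out", sim))
cli_main(c("run", "--maf", file.path(sim, "caller1.maf"),
           "--maf", file.path(sim, "caller2.maf"),
           "--gene-cn", file.path(sim, "gene_cn.tsv"),
           "--seg", file.path(sim, "segments.seg"),
           "--counts", file.path(sim, "counts.tsv"),
           "--out", run, "--seed", "11"))
```

The same interface is available from the shell via
`Rscript $(Rscript -e 'cat(system.file("cli", "bap1tools.R", package = "bap1tools"))') <subcommand> ...`
with subcommands `merge`, `compare`, `alterations`, `signature`, `score`,
`geneset-score`, `classify`, `simulate`, `run`.

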