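# editscan

Genome-wide RNA editing analysis for tumor/normal RNA-seq cohorts:
editing-site identification by a multi-stage filter cascade, differential
editing classification, functional-consequence calling, and an
editing-based prognostic risk score.

## What it does, and for whom

A-to-I RNA editing (adenosine deaminated to inosine, read as G) is a
graded, post-transcriptional counterpart of DNA mutation: every site in
every sample has an *editing degree* — the fraction of reads supporting
the edited base. For cancer transcriptomics groups working with paired
tumor/normal RNA-seq, `editscan` turns per-sample variant calls into:

- an **editing-site catalog**: candidate variants pass five filters —
  per-sample somatic-mutation removal, cohort-wide known-SNP and indel
  removal, quality thresholds (FS > 20, QD < 2, < 2 edited reads or
  < 10 total reads removed), 100%-degree artifact removal, and
  recurrence/spread rules (edited in ≥ 1% of samples; 90%-minus-10%
  degree quantile ≥ 10%) — then drop non-canonical chromosomes and
  dual-strand gene context;
- **differential classes**: *gain* sites (Fisher exact BH p < 0.05,
  edited in ≤ 5% of normals), *loss* sites (the mirror), and *dys-edited*
  sites from the paired subcohort (paired t, BH p < 0.2 and raw p < 0.01,
  with |degree change| > 0.25 in ≥ 2 pairs, same direction);
- **functional consequences**: codon-level coding changes (internal
  annotator, exhaustively tested against whole-transcript translation),
  miRNA-target rewiring of 3'UTR sites via an internal duplex scorer
  (alignment score > 140, duplex free energy < −14 kcal/mol;
  gained/lost/energy-shifted > 14 kcal/mol; consequence when > 10
  relationships change), and editing-degree/expression correlation on
  median-of-ratios-normalized counts (Pearson, BH p < 0.05);
- a **prognostic risk score** per patient,

  `Risk = Σ_i β_i · Exp_gene(i) · Edit_i` with `β_i ∈ {+1, −1}`

  the sign of a univariate Cox coefficient for each qualifying site
  (differential ∧ consequence-bearing ∧ in a gene), evaluated by
  median-split Kaplan-Meier/log-rank, grade/stage rank-sum association,
  and multivariate Cox adjustment for gender, age, BMI, grade and stage.

A fully synthetic cohort generator (`simulate_cohort()`) emulates the
statistical structure of such a cohort — planted gain/loss/dys sites,
SNP/mutation/artifact confounders, expression links, survival links —
with complete ground truth, so every stage is scored for recovery and
type-I calibration in the test suite.

## Worked example

```r
library(editscan)
library(dplyr)

cohort <- simulate_cohort(simulation_config(seed = 1))
res <- run_pipeline(cohort)

res$differential |> count(class)
#>   class        n
#> 1 dys_edit    23
#> 2 gain        60
#> 3 loss        49
#> 4 none       899

glance(res$risk_model)
#>   n_sites n_risky n_protective n_excluded
#> 1      17       7           10          6

glance(res$survival)
#>       n logrank_chisq logrank_p
#> 1    80          5.81    0.0159
```

The cohort plants 50 gain and 50 loss sites (plus 10 survival-linked
sites with a tumor-only editing pattern, hence the 60 gain calls) and 20
dys-edited sites among 2,000 candidates; the catalog keeps 1,031 sites
after filtering. The risk model retains 17 consequence-bearing
differential sites (6 excluded for unstable univariate fits), and the
median split separates survival at log-rank p = 0.016; the score stays
associated with survival after multivariate adjustment (p = 0.026 here).
`autoplot(res$survival)` draws the Kaplan-Meier curves and
`plot_editing_overview(res$annotated)` the variant-type and feature
distributions.

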