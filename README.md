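# consigamp

Genomic amplifications in cancer usually span many genes, so the clinically
relevant driver of a recurrent amplicon is rarely obvious from copy number
alone. `consigamp` implements an integrative prioritization workflow for
nominating **druggable amplified oncogene targets** from segmented copy-number
and expression data, together with the companion analyses such a study needs:
expression-based survival stratification, a reverse-phase protein array (RPPA)
consistency screen, and selectivity ranking of kinase inhibitors. A
synthetic-cohort generator with planted ground truth makes the whole pipeline
testable at desk scale, without any external download.

It is aimed at computational cancer-genomics analysts working with
CBS-segmented copy-number profiles (SEG files), gene-by-sample expression
matrices and clinical annotations.

## The method

For each gene *g* and sample *s*, segment-level log2 copy-number ratios are
aggregated to a gene-level value by an overlap-length-weighted mean of the
segments intersecting the gene body. A gene is **amplification positive** in a
sample when its gene-level log2 ratio exceeds 0.7, and its cohort frequency is
the fraction of amplification-positive samples among informative samples of a
clinical subset (by default the ER-positive tumours). Genes amplified in more
than 5% of that subset are candidates. Each candidate's **dosage effect** is
the Spearman rank correlation ρ₍g₎ between its expression and its gene-level
copy number over the same subset, and its priority score is

    score(g) = ρ(g) × ConSig(g)

where ConSig(g) ≥ 0 is a precomputed concept-signature score measuring the
gene's association with cancer-related molecular concepts (supplied as an
input table, not computed here). Candidates are filtered for druggability
against a drug–target table and ranked by the score; with ConSig scores
bounded by 2.5 the scores lie in [−2.5, 2.5].

Companion analyses:

* **Survival**: samples are split into *high* versus *rest* at the strict
  cutoff `median + 1 × MAD` (MAD with the 1.4826 normal-consistency
  constant), follow-up is administratively censored at 120 months, and groups
  are compared with in-package Kaplan–Meier, log-rank and
  Gehan–Breslow–Wilcoxon tests.
* **RPPA screen**: spots are normalized as
  `((fg − local_bg) − negctrl) / total_protein`, triplicates summarized by
  medians, arms compared per antibody by Welch *t*-tests, and antibodies with
  `p < 0.1` in *every* model comparison and a consistent direction are
  reported sorted by mean *p*.
* **Inhibitor selectivity**: compounds in a compound × kinase
  percent-inhibition matrix are ranked by activity against a chosen target;
  the off-target count of a compound is the number of kinases it inhibits
  more strongly than the target.

## Worked example

```r
library(consigamp)

cohort  <- generate_cohort(cohort_config(seed = 2026))
targets <- nominate_targets(cohort$cn, cohort$expression, cohort$consig,
                            cohort$druggability, cohort$clinical, top_k = 50)
targets
#> # A tibble: 10 × 7
#>    rank gene   amp_frequency spearman_rho consig consig_amp druggable
#>   <int> <chr>          <dbl>        <dbl>  <dbl>      <dbl> <lgl>
#> 1     1 G5_044        0.282        0.804    2.07      1.67  TRUE
#> 2     2 G2_044        0.103        0.587    2.37      1.39  TRUE
#> 3     3 G4_044        0.147        0.568    2.44      1.38  TRUE
#> 4     4 G1_044        0.0897       0.560    2.37      1.33  TRUE
#> 5     5 G3_044        0.154        0.620    2.06      1.28  TRUE
#> 6     6 G2_043        0.103        0.0983   1.56      0.154 TRUE
#> # ℹ 4 more rows
```

The five genes planted as dosage drivers (`cohort$truth$drivers`, one per
amplicon) occupy ranks 1–5: each is frequently amplified (9–28% of ER+
samples), each has a strong expression/copy-number correlation (ρ ≈ 0.56–0.80)
and a high concept score, so the product pushes them above the amplified
passenger genes, whose correlations hover near zero. `autoplot(targets)` draws
the score scatter (ρ against ConSig, point size = amplification frequency).

```r
fit <- survival_by_expression(cohort$expression, cohort$truth$survival_gene,
                              cohort$clinical)
fit$logrank
#> log-rank test: chi-square = 40.34 on 1 df, p = 2.131e-10
glance(fit$curves$high)$median_survival   # 12.6 months
glance(fit$curves$rest)$median_survival   # 50.6 months
```

The cohort plants a hazard ratio of 2 for the expression-high group of the
first driver; the high group's median survival (12.6 months) is accordingly
far below the rest (50.6 months), and both the log-rank and Gehan tests
reject. `autoplot(fit$curves$high)` draws the Kaplan–Meier step curve, and
`tidy()`/`glance()` return the per-time table and test summaries.

File-level runs of the same workflows are available as `run_nomination()` and
`run_survival()`, which also write ranked-target/curve TSVs and run logs.

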