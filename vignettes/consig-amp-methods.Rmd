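---
title: "Methods: amplified-driver nomination and its companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplified-driver nomination and its companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consigamp)
```

## The problem and the model

Recurrent genomic amplifications in tumours span whole chromosomal regions,
so copy-number frequency alone cannot distinguish the driver gene of an
amplicon from its passengers. This package ranks candidates by combining
three signals that a driver should show simultaneously: (i) recurrent
amplification in the clinically relevant subset, (ii) a *dosage effect* —
expression that tracks DNA copy number across samples — and (iii) prior
evidence of cancer relevance summarised in a non-negative concept-signature
(ConSig) score supplied as an input table. The priority score of gene $g$ is

$$\mathrm{score}(g) = \rho_g \times \mathrm{ConSig}(g),$$

where $\rho_g$ is the Spearman correlation between expression and gene-level
copy number. The product form means a gene scores highly only when both
signals agree; a passenger inside a frequent amplicon has $\rho_g \approx 0$
and scores near zero regardless of its concept score.

Assumptions worth stating explicitly: copy-number input is segment-level
log2 ratio data (circular-binary-segmentation output) on a scale where 0 is
copy-neutral; expression and copy number share sample identifiers; the
concept score and druggability tables are trusted externally curated inputs
joined by gene symbol (case-insensitive exact match, no alias resolution).

## Parameters that matter

| Parameter | Default | Units / scale | Rationale |
|---|---|---|---|
| `amp_threshold` | 0.7 | log2 ratio | conventional cutoff for focal amplification on segmented SNP-array ratios; applied with strict `>` |
| `min_freq` | 0.05 | fraction | candidates must be amplified in *more than* 5% of the subset (strict `>`); denominator = informative (non-missing) samples |
| `subset_rule` | `er_pos` | – | frequency and correlation are computed on the same clinical subset |
| MAD constant | 1.4826 | – | normal-consistency constant; the survival cutoff is `median + 1 × MAD`, strict `>` |
| `max_months` | 120 | months | administrative censoring at ten years: events beyond the cap become censored at the cap |
| RPPA `alpha` | 0.1 | – | per-comparison screen level; no multiplicity correction because the screen is descriptive and requires replication across every comparison |

## Coordinate and format conventions

SEG files are 1-based inclusive on disk and converted to 0-based half-open
internally (`start−1`, `end`), which makes the conversion an exact bijection
(verified by a write/read round-trip test). Gene models are BED-like and
0-based half-open on disk, kept as-is. Chromosome names are compared after
stripping an optional `chr` prefix, case-insensitively. Readers fail loudly:
missing columns, non-numeric cells, ragged rows, duplicate identifiers and
overlapping segments are errors naming the offending column, line or pair —
never silently coerced.

## Numerical choices

* **Gene-level aggregation** is the overlap-length-weighted mean of segment
  ratios over the gene body. It is order-independent, reduces to the segment
  value when one segment covers the gene, and equals a per-base mean — the
  property the test suite checks against a brute-force per-base oracle.
  Strand is ignored; a gene with no overlapping segment is missing, and
  missingness propagates through calls and frequencies (frequency
  denominators count informative samples only).
* **Strict inequalities** everywhere a threshold appears (`> 0.7`,
  `> 5%`, `> median + MAD`, off-target `>` target), so boundary values never
  change sides depending on floating-point formatting.
* **Spearman with ties** is computed as the Pearson correlation of
  average-rank vectors over pairwise-complete samples. Genes with fewer than
  3 pairs or a constant vector get an explicit undefined result (`NA` with a
  reason) and are excluded from the ranking with the reason logged — never
  imputed as 0.
* **Negative correlations are retained** with negative scores rather than
  clamped. The descending sort pushes them to the bottom, which reproduces a
  non-negative observed score range on driver-like data without ad-hoc
  truncation, while preserving information for diagnostics.
* **Tie-breaking** in the ranking is total and deterministic: score
  descending, then $|\rho|$ descending, then gene symbol ascending. The
  inhibitor ranking uses activity descending, then off-target count
  ascending, then compound id.
* **Survival tests** share one weighted log-rank implementation: at each
  distinct event time the observed events in one group are compared with the
  hypergeometric expectation given the pooled risk set; weight 1 gives the
  log-rank test, weight = pooled number at risk gives the Gehan–Breslow
  generalized Wilcoxon. Ties between censorings and events at one time keep
  the censored subjects at risk for that event. Zero total variance is an
  explicit error, not a zero statistic. *P* values are chi-square upper
  tails with one degree of freedom. A caveat discovered while testing: a
  *new* subject censored after the last event does join every risk set and
  legitimately changes the statistic; the invariance that does hold — and is
  tested — is that a censoring time already beyond the last event can be
  moved arbitrarily.
* **Welch rather than Student** for the RPPA per-antibody comparison: arm
  variances in small knockdown experiments are routinely unequal, Welch is
  valid either way, and with three samples per arm the difference is the
  degrees of freedom, which the test suite pins against the
  Welch–Satterthwaite formula.
* **Negative normalized RPPA intensities** (negative-control signal
  exceeding the background-corrected foreground) are retained and flagged
  rather than floored; downstream medians are robust to them.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` plants, by default, five focal amplicons (eight
consecutive genes each, one per chromosome of a 5 × 100-gene genome) at
prevalences 0.12–0.25, the range of ER+ amplification frequencies reported
for well-known amplified breast-cancer oncogenes. Amplified regions get log2
ratios uniform on [1, 2] against background segments with SD 0.15, and
segment breakpoints are drawn per sample so boundaries do not align across
samples — deliberately stressing the gene-level aggregation. One gene per
amplicon is the planted driver with dosage slope 1.5 expression units per
log2 unit; all other genes have slopes near zero (SD 0.05), so passengers
are amplified but not dosage-responsive. Concept scores are uniform on
[2, 2.5] for drivers and [0.05, 1.8] for the background, keeping all scores
within the 0–2.5 range on which the score bound $|\mathrm{score}| \le
\mathrm{ConSig}$ is asserted. Survival times are exponential with hazard
0.015/month times a hazard ratio of 2 for the expression-high group of the
first driver (the simplest model consistent with a proportional-hazards
comparison), with independent uniform censoring on [0, 180] months.

The RPPA generator models spot-level measurement noise as a contaminated
normal — a tight core plus occasional outlier spots (15% at ~6× the core
SD) — which is the error regime that motivates triplicate medians in this
assay, and the reason medians rather than means are the replicate summary.
The planted shift is `effect_size` times the *total* spot-noise SD, applied
in a fixed direction in the perturbed arm of every comparison; arms are
otherwise exchangeable (no extra biological between-sample term), so the
generator models technical reproducibility of an engineered perturbation.
The kinase-matrix generator draws background inhibition from a scaled
Beta(1.5, 6) (right-skewed, mean ≈ 20%) and overwrites planted cells
exactly, so planted off-target counts hold by construction.

Not emulated: whole-genome scale, GC or batch artefacts, subclonal or
allele-specific copy number, non-proportional hazards, antibody
cross-reactivity, and dose–response structure in the inhibition matrix.
Passing tests on this generator therefore demonstrate correctness of the
statistical machinery and recoverability under the planted model — not
performance on any real cohort.

All generator randomness flows from a single integer seed through
deterministically derived per-component sub-streams, so every emitted file
is byte-identical across reruns of one seed (tested).

## Problem sizes

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen to make every stochastic check well-powered while keeping runs
fast: cohorts of 200 samples × 500 genes for nomination and calibration
checks; 50 random toy genomes (≤10 genes, ≤50 segments) for the per-base
oracle; 100 random vectors (n ≤ 50) for the Spearman oracle; 2000/500
replicates of two 100-patient arms for log-rank size and power; 200
antibodies with five planted shifts for the RPPA screen; and a 158 × 234
inhibition matrix for the selectivity ranking.

## Known limitations

The nomination score is a ranking heuristic, not a calibrated probability;
no uncertainty is attached to the ranks. The frequency filter is marginal
for amplicons whose true prevalence sits near `min_freq` relative to the
subset's binomial noise. Survival analysis is restricted to the two-group
unadjusted setting (no Cox regression or covariate adjustment), and the RPPA
screen deliberately reports descriptive, uncorrected hits that require
replication across comparisons rather than controlling a family-wise error
rate.
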