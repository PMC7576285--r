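---
title: "Immune-risk stratification from gene–lncRNA differential co-expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-risk stratification from gene-lncRNA differential co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immrisk)
```

## The problem

Long non-coding RNAs (lncRNAs) are increasingly recognised as regulators of
the tumour immune microenvironment, but for most cancers it is unknown which
lncRNAs matter for which immune cell types. `immrisk` implements a
computational pipeline that, starting from bulk expression profiles of
tumour and adjacent-normal tissue, (i) identifies tumour-specific
immune-cell-population marker genes ("ICPR genes") and lncRNAs, (ii) finds
gene–lncRNA pairs whose co-expression is rewired in tumours, (iii)
assembles those pairs into per-population bipartite networks, and (iv) uses
the networks to assign each patient a rank-based immune-risk score that
stratifies the cohort into three prognosis groups compared by
Kaplan–Meier/log-rank analysis.

The pipeline operates on three inputs: a features × samples expression
matrix (coding genes and lncRNAs, tumour and normal samples), a catalogue of
marker gene sets for 17 immune cell populations (B cells, eosinophils,
macrophages, mast cells, NK CD56bright/CD56dim cells, neutrophils, T helper
cells, Tcm, Tem and Tfh cells, activated and induced dendritic cells,
activated CD8 T cells, gamma-delta T cells, Tregs and cytotoxic cells), and
a clinical follow-up table.

## The model, stage by stage

### Preprocessing

Features containing zero expression values are removed (configurable via
`zero_filter_frac`; the default removes a feature with *any* zero, the
strictest reading of the usual "zeros removed" preprocessing statement and
the one that makes a pseudocount irrelevant for retained features), then
values become `log2(x + pseudocount)` with pseudocount 1. All downstream
statistics — t-tests, Pearson correlations, expression ranks — operate on
this log2 scale.

### Differential expression

Every feature gets a two-sided Welch (unequal-variance) t-test between
tumour and normal samples. Welch rather than Student is the deliberate
choice: tumour cohorts are typically much larger than their normal
comparators (hundreds versus tens) and have no reason to share variances.
Genes are called tumour-specific at raw `p < 0.05`, lncRNAs at the stricter
`p < 0.01`; the two class-specific thresholds are `p_gene` and `p_lnc` in
`pipeline_config()`. Benjamini–Hochberg-adjusted p-values are computed and
stored so a more conservative analysis is one switch away
(`use_adjusted_p = TRUE`), but the default significance flags use raw
thresholds, matching the procedure the pipeline reimplements. Direction is
`up` when the tumour mean exceeds the normal mean; exact ties are labelled
`down` (a deterministic tie-break; tied features are never significant).
The lncRNA test is run once globally, not per population — lncRNAs are not
members of the population gene sets.

### Differential co-expression

For each population, every tumour-specific member gene is correlated
(Pearson) with every tumour-specific lncRNA, separately within tumour and
within normal samples. The screening statistic is
`delta = |r_tumor − r_normal|`, the absolute change in correlation. Two
thresholds govern the stage, both strict inequalities:

| parameter | default | role |
|---|---|---|
| `delta_screen` | 0.3 | retain a pair for reporting/histograms |
| `delta_network` | 0.7 | promote a pair to a network edge |

Screened pairs carry a qualitative change pattern:
`negative_to_positive` and `positive_to_negative` for sign flips (a zero
correlation counts as non-negative), and `same_sign_strengthened` /
`same_sign_weakened` otherwise. Correlation p-values for both groups are
recorded but not filtered on by default (`pair_p_max` enables an optional
filter), since the screening rule is the delta, not the per-group
significance.

Edges form per-population bipartite networks (genes on one side, lncRNAs on
the other) plus an integrated network pooling all populations; a
gene–lncRNA edge recurring in several populations collapses to its
maximum-delta instance there, because an untyped graph cannot hold
duplicate edges and the strongest signal is the informative one. Degree
analysis ranks hubs (ties broken lexicographically, so output is
deterministic), and scale-freeness is assessed the conventional way: an
ordinary least-squares fit of `log10(frequency)` against `log10(degree)`
over degree values with nonzero frequency, reporting slope and R². The fit
refuses distributions with fewer than three distinct degree values rather
than returning a meaningless R².

The pair histogram pools populations, so a pair recurring in two
populations is counted twice; this matches reporting pair counts per
population and keeps the two views consistent.

### Rank-based immune-risk scoring

This is the heart of the pipeline. For each network feature, tumour
patients (normals are excluded — risk is defined for patients) are ranked
by expression from high to low. With `N` patients, one boundary index
`k = ceiling(0.30 · N)` splits the ranking into a top block (ranks `1..k`)
and the rest:

* **up-regulated** features are a risk for the patients *outside* the top
  block (the bottom 70%) — patients failing to express an up-regulated
  network feature strongly;
* **down-regulated** features are a risk for patients *inside* the top
  block (the top 30%).

Because 70% and 30% are complements, a single boundary index governs both
rules; `up_risk_frac`/`down_risk_frac` are validated to sum to 1. The
boundary arithmetic (ceil, and which side the boundary rank falls on) is
not canonical anywhere, so the package fixes one convention, asserts it in
tests, and exposes the fraction as configuration. Expression ties are
broken by patient id, ascending — reproducibility over elegance.

A population is a **risk population** for a patient when strictly more
than 50% (`pop_risk_frac`) of its network's features (genes *and* lncRNAs
— the denominator is the full node set) are risk features for that
patient. Populations whose networks came out empty are dropped from
scoring entirely, including from the denominator of the group bounds.
Finally the per-patient count of risk populations maps to three groups:

| group | risk populations (defaults) |
|---|---|
| `min_immune` | 0–4 |
| `media_immune` | 5–9 |
| `multi_immune` | 10–17 |

`two_group_split()` supports the boundary-6/boundary-7 two-group
sensitivity analyses (high side: `count >= boundary`).

### Survival

Kaplan–Meier product-limit curves per group and the standard unweighted
k-sample log-rank test (`df = k − 1`), both delegated to the `survival`
package behind the module interface and verified in the test suite against
a brute-force product-limit oracle enumerated over all censoring patterns
of up to eight records. Deaths precede censorings at tied times. Patients
without clinical records are dropped with a logged count. The pipeline is
endpoint-agnostic: it analyses whatever time/event the clinical table
encodes.

## The synthetic-data generator

`sim_config()` / `simulate_cohort()` generate cohorts with planted ground
truth for every stage. Design choices, and what they do and do not
emulate:

* **Normal generation on the log2 scale** (mean `base_mean = 8`, sd
  `noise_sd = 1`). Every statistic the pipeline computes (t, Pearson,
  ranks) operates on log2 values, so emulating raw count distributions
  would add realism the statistics never see. Consequently the generator
  says nothing about count overdispersion, library-size effects or
  zero-inflation, and passing tests do not certify behaviour on raw counts.
  The emitted matrix is `2^signal` so a run exercises the real
  preprocessing path; the `log2(x+1)` transform is monotone and nearly
  affine at these levels, so planted ranks are preserved exactly and
  planted correlations to within noise.
* **Default cohort 300 tumour / 50 normal, 17 populations × 10 genes, 200
  lncRNAs** — a large tumour arm against a small normal arm, the asymmetry
  the Welch choice anticipates, at a size where a full pipeline run takes
  about a second.
* **DE effects** of ±2 log2 units (4-fold) on a `frac_de = 0.3` subset,
  with random direction.
* **Planted pairs** (3 per population) are built from a shared latent
  factor: both members are `sqrt(r)·z + sqrt(1−r)·ε`, giving within-group
  correlation `r = 0.9` in tumour and `−0.9` (or 0, via
  `r_normal = "zero"`) in normal, i.e. planted deltas near 1.8. Pair
  members are always given a DE effect so the pairs can survive the DE
  filter and reach the network stage in end-to-end runs. Pairs are
  feature-disjoint (a gene or lncRNA joins at most one planted pair) to
  keep planted correlations exact; the price is that default integrated
  networks are degree-regular, so the power-law fit correctly refuses them
  and scale-free behaviour is tested on dedicated synthetic degree
  sequences and preferential-attachment graphs instead.
* **Survival** is exponential with hazard
  `baseline_hazard · hazard_multiplier^count`, where `count` is the
  patient's true risk-population count (derived by applying the rank rules
  to the generated matrix with the planted networks and directions — the
  generator's truth is consistent with its matrix by construction).
  `baseline_hazard` defaults to `log(2)/730` per day (two-year median for
  a zero-count patient). The default `hazard_multiplier = 1.3` makes
  immune-diverse patients die faster; a value below 1 produces the
  opposite sign, and detection tests are two-sided, so only association —
  not sign — is asserted. Censoring marks a `censor_rate = 0.3` fraction
  of patients, censored at a uniform fraction of their drawn event time.

`simulate_survival()` seeds its own stream at `seed + 1`, so expression
and survival are independently reproducible regardless of call order.

## Numerical and validation choices

* Vectorised Welch statistics are computed from group means/variances with
  the t-distribution; the test suite pins them to `stats::t.test` and a
  textbook-formula oracle at `1e-12`. Zero-variance-in-both-groups rows are
  defined (`t = 0, p = 1` on equal means) rather than errors.
* Pearson screening uses matrix `cor()` with p-values from the
  t-distribution on `n − 2` df; the scalar `pcc()` delegates to
  `cor.test()` and both are pinned to a direct covariance-formula oracle.
  Constant features are excluded from screening with a warning (their
  correlation is undefined).
* The risk module is validated by exact equivalence, on hundreds of random
  small instances including ties, against an independent brute-force
  implementation of the four scoring steps that ranks by pairwise counting
  (O(N²)) instead of sorting.
* Test and acceptance problem sizes — 200 oracle instances, 10 × 1000
  features for null calibration, 100/100 samples for pair recovery, 1000
  null log-rank replicates, 20 end-to-end seeds at 300/50 — were chosen as
  the smallest sizes at which the binomial error bands around the asserted
  rates are meaningfully narrow; the whole suite runs in well under a
  minute.

## Known limitations

* Raw significance thresholds (no multiple-testing correction) are the
  default because they are the procedure being reimplemented; the BH
  columns are provided for users who want rigour over fidelity.
* The bundled 17-population GMT uses real population names with a compact
  synthetic marker membership; analyses of real data should supply a
  published marker catalogue.
* The generator plants linear (Gaussian, latent-factor) co-expression;
  nonlinear or rank-only dependence, batch effects and tumour purity are
  out of scope, and sensitivity/precision results transfer to real data
  only to the extent that rewired pairs are approximately linear.
* Group bounds (4, 9) assume 17 scored populations; if many population
  networks come out empty the bounds remain as configured and may need
  adjusting to the number of populations actually scored.
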