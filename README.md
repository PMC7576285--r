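# immrisk

Immune-related lncRNA co-expression networks and rank-based immune-risk
stratification for tumour cohorts.

## What it does

Tumours rewire the co-expression between immune marker genes and long
non-coding RNAs (lncRNAs). `immrisk` turns a tumour/normal bulk expression
matrix, a catalogue of marker gene sets for 17 immune cell populations, and
a clinical follow-up table into:

1. **Tumour-specific features** — per-feature Welch t-tests call
   tumour-specific immune-population marker genes (p < 0.05) and lncRNAs
   (p < 0.01), with direction (up/down in tumour).
2. **Differential co-expression networks** — for each population, every
   tumour-specific gene–lncRNA pair gets a Pearson correlation within
   tumour (`r_T`) and within normal (`r_N`) samples; pairs are screened by
   `Δ = |r_T − r_N| > 0.3`, classified (sign flips vs same-sign
   strengthening/weakening), and pairs with `Δ > 0.7` become edges of
   bipartite per-population networks plus an integrated network with hub
   (degree) analysis and a log–log power-law fit of the degree
   distribution.
3. **Per-patient immune-risk groups** — for each network feature, tumour
   patients are ranked by expression (high to low; `k = ⌈0.3·N⌉`):
   an up-regulated feature is a *risk feature* for patients ranked below
   the top block (the bottom 70%), a down-regulated feature for patients
   inside it (the top 30%). A population is a *risk population* for a
   patient when more than 50% of its network features are risk features,
   and the count of risk populations stratifies patients into
   `min_immune` (0–4), `media_immune` (5–9) and `multi_immune` (10–17)
   groups.
4. **Survival comparison** — Kaplan–Meier curves per group and the
   unweighted log-rank test (three-group, plus two-group splits at
   boundaries 6 and 7).

A synthetic-data generator (`sim_config()`, `simulate_cohort()`) plants
differential expression, rewired gene–lncRNA pairs and
risk-count-dependent exponential survival, so every stage can be validated
against known ground truth.

## Worked example

```r
library(immrisk)

scfg <- sim_config(n_tumor = 120, n_normal = 40, seed = 3)
sim  <- simulate_cohort(scfg)                      # expression + gene sets + clinical
run  <- run_pipeline(sim$expression, sim$sets, sim$clinical,
                     pipeline_config(seed = 3))
run
#> Immune-risk pipeline run
#>   features: 370 kept of 370; screened pairs: 975; integrated edges: 51
#>   patients: 120 (min_immune=19, media_immune=91, multi_immune=10)
#>   three-group log-rank p = 0.003884

run$survival$three_group
#> Log-rank test: chi-square 11.102 on 2 df, p = 0.003884 (3 groups, n = 120)

head(run$profiles, 4)
#>   patient_id risk_population_count        group
#> 1       T001                     1   min_immune
#> 2       T002                     7 media_immune
#> 3       T003                     8 media_immune
#> 4       T004                     5 media_immune
```

Reading the output: all 370 simulated features survive the zero filter; 975
gene–lncRNA pairs change correlation by more than 0.3 between tumour and
normal; 51 of them exceed the 0.7 network threshold (these are the planted
rewired pairs). Each of the 120 tumour patients is scored against the 17
population networks and lands in one of the three immune-risk groups; the
simulated hazard increases 1.3-fold per risk population, and the log-rank
test recovers that planted association (p = 0.004).

File-based runs use `run_pipeline_files("run.yaml")`, where the YAML lists
the input paths (`expression`, `class_map`, `gene_sets`, `clinical`), an
`out_dir`, and optional `config` overrides; every stage output is persisted
as TSV/JSON together with a run manifest. `write_simulation()` writes a
simulated cohort in exactly those formats.

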