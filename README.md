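# ecoassembly

Phylogenetic null models for inferring the ecological processes that
assemble microbial communities.

Given a rarefied amplicon (ASV) count table, a rooted phylogeny over the
same taxa, and sample metadata, `ecoassembly` classifies every pair of
samples into one of five assembly processes and aggregates the calls into
process fractions, overall or per calendar month. It is aimed at
microbial-ecology datasets — e.g. long-term marine phytoplankton
metabarcoding surveys — where the balance between deterministic selection
and stochastic dispersal/drift is the question of interest.

## The framework

Two null-model statistics drive the inference, each against 999 (by
default) random shufflings of the phylogeny's tip labels:

- **NRI** (within samples): `NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)`,
  where MPD is the mean pairwise cophenetic distance among a sample's taxa.
  NRI > 0 — phylogenetic clustering (environmental filtering); NRI < 0 —
  overdispersion.
- **βNRI** (between samples): the analogous z-score of βMPD, the mean
  cophenetic distance over all cross pairs of two samples' taxa (not
  sign-flipped).

A taxonomic Raup–Crick metric on Bray–Curtis dissimilarity (**RC_bray**,
rescaled to [−1, 1]) separates the stochastic processes: null communities
fix each sample's richness and total reads, redraw membership by occupancy
frequency and refill reads by dataset-wide relative abundance.

The decision tree per sample pair:

| condition | process |
|---|---|
| βNRI < −2 | homogeneous selection |
| βNRI > +2 | heterogeneous selection |
| otherwise, RC_bray > 0.95 | dispersal limitation |
| otherwise, RC_bray < −0.95 | homogenizing dispersal |
| otherwise | drift |

The framework presumes phylogenetic signal in environmental niches;
`niche_values()` + `mantel_correlogram()` test that prerequisite
(positive short-distance-class correlations = signal).

A synthetic-community generator (`scenario_config()`,
`assemble_communities()`) builds datasets with known ground truth under
each of the five processes — birth–death tree, Brownian niche traits,
Gaussian environmental filtering, log-normal metacommunity — so the whole
pipeline is testable without any external data. See the vignette
(`vignettes/community-assembly.Rmd`) for the model details and design
choices.

## Worked example

Simulate a community assembled under homogeneous selection, run the full
pipeline, and look at the inferred processes:

```r
library(ecoassembly)

cfg <- run_config(
  scenario = scenario_config("homogeneous_selection", seed = 101),
  n_reps = 199, signal_variable = "temperature",
  out_dir = "demo_run", seed = 1)
res <- run_pipeline(cfg)

res$summary[, c("group_label", "n_pairs",
                "frac_homogeneous_selection", "frac_drift")]
#>   group_label n_pairs frac_homogeneous_selection frac_drift
#> 1         ALL     190                          1          0

head(res$turnover[, c("sample_a", "sample_b", "beta_nri", "rc_bray",
                      "process")], 4)
#>   sample_a sample_b  beta_nri    rc_bray               process
#> 1     S001     S002 -21.60074 -0.9949749 homogeneous_selection
#> 2     S001     S003 -20.55992 -1.0000000 homogeneous_selection
#> 3     S002     S003 -21.93980 -1.0000000 homogeneous_selection
#> 4     S001     S004 -20.85428 -0.9899497 homogeneous_selection

head(res$alpha[, c("sample_id", "richness", "shannon", "faith_pd", "nri")], 4)
#>   sample_id richness  shannon faith_pd      nri
#> 1      S001       45 3.285280 163.7344 20.76572
#> 2      S002       47 3.286871 165.1479 21.00406
#> 3      S003       44 3.271973 163.4705 21.66469
#> 4      S004       48 3.337848 170.2381 20.72362
```

Every pair shows strongly negative βNRI (far below −2), so all 190 pairs
classify as homogeneous selection — the process the data were generated
under — and every sample is strongly phylogenetically clustered (NRI ≈ 21).
The correlogram on `temperature` (a decoy variable that played no role in
assembly) shows no significant short-distance correlation, as it should.

All artifacts (rarefied table, alpha/NRI table, pairwise turnover records,
process summaries, correlogram, truth-vs-inferred confusion table, run log
with every seed and drop) are written under `out_dir`; identical configs
produce byte-identical outputs.

Real data enter through the same pipeline via file paths:

```r
cfg <- run_config(table_path = "counts.tsv", tree_path = "tree.nwk",
                  metadata_path = "metadata.csv", depth = "min",
                  grouping = "month", out_dir = "field_run", seed = 1)
```

A thin CLI wrapper with the same options lives at
`inst/scripts/run-pipeline.R`.

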