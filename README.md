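# nversa

Nitrogen-cycle metabolic versatility profiling of shotgun metagenomes.

Microbial nitrogen cycling is conventionally described one pathway per
organism — nitrifiers nitrify, diazotrophs fix N₂. Gene-centric metagenomics
makes it possible to ask how often that picture is wrong: given which
nitrogen-cycle gene families each species carries, how many species encode
**two or more** of the eight nitrogen-transformation pathways (ammonia
assimilation, assimilatory nitrate reduction, dissimilatory nitrate →
nitrite, dissimilatory nitrite → ammonia, denitrification, nitrification,
nitrogen fixation, anammox)? `nversa` implements that analysis as a
reusable, tested pipeline for microbial ecologists working with per-sample
gene-family annotation tables — the tabular output of searching assembled
ORFs against a curated nitrogen-cycle gene database (NCycDB-style) with
taxonomy from NR.

## The method

For species *i* with gene repertoire *G\_i* and an ontology mapping gene
families to pathways *P(g)*:

* **Occupancy rule** — species detected in fewer than 2 distinct samples of
  an ecosystem are discarded (`min_prevalence`, default 2).
* **Pathway profile** — an 8-bit presence vector:
  pathway *p* is encoded iff ∃ *g* ∈ *G\_i* with *p* ∈ *P(g)*, evidence
  pooled across samples. The **degree** *k\_i* is the popcount; a species is
  **versatile** iff *k\_i* ≥ 2. Genus profiles are the union (OR) of member
  species' vectors.
* **Combination counts** — each species tallied once under its *exact*
  pathway set (UpSet "distinct" semantics over the 255 non-empty subsets).
* **Guilds** — ammonia-oxidizing archaea/bacteria (AOA/AOB: `amoCAB`,
  `pmoCAB`, `hao`), nitrite oxidizers (NOB: `nxrAB`) and nitrogen fixers
  (`nifHDK`), with precedence AOA > AOB > NOB so the three nitrifier labels
  partition; "pure" guild members have degree 1 on the guild's defining
  pathway.
* **Ecosystem comparison** — exact-name overlap of species registries
  (shared count, one-sided percentages, Jaccard).

A synthetic-community generator (per-species occupancy ψ ~ Beta(α, β),
per-gene detection probability δ) provides ground truth for end-to-end
validation, plus deterministic "exact marginal" reference communities used
by the test suite.

## Worked example

```r
library(nversa)

soil <- soil_reference_fixture()      # deterministic reference community
filtered <- apply_prevalence_filter(soil)
profiles <- build_profiles(filtered, level = "species")
profiles
#> <profile_set> species level, 'soil': 5363 taxa, 2065 versatile

degree_distribution(profiles)$counts
#>    1    2    3    4    5    6    7    8
#> 3298 1021  490  292  201   46   14    1

versatile_fraction(degree_distribution(profiles))[c("count", "percent_raw")]
#> $count
#> [1] 2065
#> $percent_raw
#> [1] 38.50457

head(subset(combination_counts(profiles), size >= 2), 2)
#>   combo                                          size     n
#> 1 AMMONIA_ASSIMILATION+ASSIM_NITRATE_REDUCTION      2   337
#> 2 AMMONIA_ASSIMILATION+DISSIM_NITRITE_TO_AMMONIA    2   215

guilds <- assign_guilds(filtered, profiles)
s <- guild_summary(guilds, profiles, "NFIXER")
c(total = s$n_total, pure = s$n_pure, pct_versatile = s$percent_versatile)
#>         total          pure pct_versatile
#>           106            15            86
```

Of 5363 nitrogen-transforming species, 2065 (38.5%) encode at least two
pathways; the commonest versatile repertoire pairs ammonia assimilation
with assimilatory nitrate reduction (337 species); and of 106 nitrogen
fixers only 15 are "pure" fixers — 86% also encode other nitrogen
pathways.

`run_pipeline()` orchestrates the whole analysis for one or more
ecosystems and writes per-ecosystem TSV/JSON artifacts plus a
`summary.json`; `inst/scripts/nversa-report.R` is a command-line wrapper
over `generate_community()` and `run_pipeline()`.

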