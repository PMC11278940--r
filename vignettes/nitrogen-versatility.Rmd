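---
title: "Profiling nitrogen-metabolic versatility from gene-family annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling nitrogen-metabolic versatility from gene-family annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nversa)
```

## The question and the model

`nversa` asks, for a set of metagenomic samples from one ecosystem, which
microbial species encode which of the eight nitrogen-transformation
pathways, and how common multi-pathway ("versatile") repertoires are. The
unit of evidence is a *detected gene occurrence*: one row of an annotation
table saying that gene family *g* of species *s* was found in sample *j*.
Such tables are what one obtains by calling ORFs on assembled contigs,
clustering them into a non-redundant gene set, and annotating against a
curated nitrogen-cycle gene database for function and NR for taxonomy.
`nversa` starts where that annotation ends; it performs no sequence
analysis itself.

The model is deliberately simple and fully deterministic:

1. **Occupancy rule.** A species is treated as a genuine community member
   only if it is detected in at least `min_prevalence` distinct samples
   (default 2, i.e. "more than one sample"). This is assessed on any
   annotation record of the species — including gene families the pathway
   ontology does not map — because the rule is about the reliability of the
   species call, not about any particular pathway.
2. **Pathway assignment.** After filtering, evidence is pooled across all
   samples: species *s* encodes pathway *p* iff at least one of its records
   anywhere carries a gene mapping to *p*. Pooling is intentional — a
   species does not need to show its nitrification gene in every sample to
   be a nitrifier. Species whose genes are all unmapped are dropped from
   profiling (each unknown gene warns once when asked to).
3. **Versatility.** The profile is an 8-element boolean vector in a fixed
   canonical pathway order; its popcount is the degree; degree ≥ 2 defines
   versatility. Genus-level profiles are the union (logical OR) of member
   species' vectors, so a genus whose species are all single-pathway
   specialists in *different* pathways is itself versatile — that is the
   property the genus-level statistic is meant to capture.
4. **Combinations.** Combination counts use exact-set (UpSet "distinct")
   semantics: every species is counted exactly once, under its precise
   pathway subset. Ranked output breaks ties by smaller subset first, then
   by canonical pathway order, so ranking is deterministic.
5. **Guilds.** Nitrifiers are species carrying ammonia-oxidation evidence
   (`amoCAB`, `pmoCAB`, `hao`) or nitrite-oxidation evidence (`nxrAB`);
   fixers carry `nifHDK`. AOA/AOB/NOB are made a partition by precedence:
   archaeal ammonia-oxidation carriers are AOA; non-archaeal ones AOB; of
   the rest, `nxr` carriers are NOB. Species with both ammonia- and
   nitrite-oxidation genes (comammox-like) keep their precedence label and
   are flagged `dual_evidence`; species whose only ammonia-oxidation
   evidence is `pmo` are flagged `pmo_only`, since `pmo` may equally mark a
   methanotroph. "Pure" guild membership is defined at the *pathway* level
   (degree 1 on the defining pathway), not the gene level, for consistency
   with the versatility definition. The nitrogen-fixer call is an
   independent flag that may co-occur with a nitrifier label.

## The gene→pathway ontology

Annotation databases do not agree on a single gene→pathway table, and the
mapping is a scientific choice, so it is externalized: a two-column TSV
(`gene_family`, `pathway`) that users can override wholesale per gene. The
shipped default covers 46 widely used marker families. Placements follow
standard usage: `amo`/`pmo`/`hao`/`nxr` under nitrification, `nif` under
fixation, `nirK`/`nirS`/`nor`/`nosZ` under denitrification,
`narGHI`/`napAB` under dissimilatory nitrate→nitrite (only there — some
schemes also count them toward denitrification; users who prefer that remap
them via TSV), `nirBD`/`nrfAH` under DNRA, `nasAB`/`narB`/`nirA`/`NR`
under assimilatory nitrate reduction, and `hzs`/`hdh`/`hzo` under anammox.
The ammonia-assimilation list (`glnA`, `gltBD`, `gdhA`, `ureABC`) is the
most judgment-laden entry: database category schemes differ on where
organic-nitrogen turnover ends and ammonia assimilation begins, and the
urease genes in particular could be argued either way. The whole list is
overridable for exactly that reason.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_prevalence` | 2 samples | occupancy rule; 1 disables filtering |
| `other_threshold` | 2 species | taxon labels below this merge into "Other" |
| `ontology path` | builtin TSV | gene→pathway mapping override |
| `occupancy_alpha`, `occupancy_beta` | 2, 2 | Beta prior of per-species sample occupancy ψ |
| `detection_prob` (δ) | 1 | per-gene, per-occupied-sample detection probability |
| `genes_per_pathway` | 1–3 | marker genes per owned pathway in simulations |

Percentages shown to users are rounded to the nearest integer, half away
from zero; every rounded figure is accompanied by its raw value in the
returned objects, and all conclusions in the test suite are asserted on
computed values, not re-rounded ones.

## The synthetic generator

`generate_community()` emulates the *downstream tabular structure* of a
real annotation run: species draw a taxon, a pathway repertoire (either
independent per-pathway inclusion probabilities conditioned on non-empty,
or an explicit repertoire distribution), marker genes for each owned
pathway, an occupancy probability ψ ~ Beta(α, β), per-sample presence
Bernoulli(ψ), and per-gene detection Bernoulli(δ) in each occupied sample.
Default inclusion probabilities are skewed the way soil communities are
(ammonia assimilation common, anammox rare, mean degree well under 2).

What it does **not** model: phylogenetic correlation of repertoires
(relatives share pathways in real data), abundance (counts are ignored
downstream anyway), chimeric assembly and misannotation (detection noise
is independent per gene, real errors are structured), and taxonomy errors.
Passing recovery tests therefore show the pipeline is correct *given its
inputs*; they say nothing about annotation quality upstream.

Alongside the stochastic generator, `community_from_blocks()` and the two
reference builders (`soil_reference_fixture()`,
`marine_reference_fixture()`) construct noiseless communities realizing
exact marginal counts — every species in exactly 2 of 3 samples, one
marker gene per encoded pathway, pathway identities chosen in canonical
order, lineages assigned so that the versatile pool has a prescribed
composition. These are the worked examples of the test suite: communities
for which every downstream statistic is known by construction, at the same
scale as a real soil (5363 species) and marine (9117 species) analysis.

## Numerical and degenerate-input choices

* Prevalence filtering that would remove *every* species raises an error
  rather than returning an empty table; downstream statistics are
  undefined on empty sets and an empty result is always a pipeline
  mistake, not an answer.
* `versatile_fraction()` on an empty distribution errors for the same
  reason; an empty *guild*, by contrast, yields a zero summary, because
  "no AOA detected" is a legitimate result.
* Duplicate (sample, gene, species) rows merge by summing counts;
  zero-count and species-less rows are dropped with a tally; unparseable
  counts are a hard error naming the line.
* Lineages accept both bare and `d__`-prefixed 7-rank strings
  (auto-detected); short lineages pad with empty ranks; more than 7 fields
  is an error.
* Gene symbols are case-insensitive keys (`NifH` ≡ `nifh`); display names
  keep their first-seen capitalization.
* All randomness flows through a single integer seed in the generator
  config; identical config + seed gives byte-identical written tables.

## Design choices that were genuinely open

* **"More than one sample"** is pinned to ≥ 2 distinct samples per
  species, any gene. One could instead require ≥ 2 detections per gene or
  per pathway; that stricter reading would interact with the pathway-union
  rule and was rejected for opacity.
* **Genus aggregation by union** (rather than "genus is versatile iff it
  contains a versatile species") was chosen because the genus-level
  question is about the repertoire of the lineage, not of any single
  member; the two definitions demonstrably differ and the union form is
  asserted in tests (every genus containing a versatile species is
  versatile, but not conversely).
* **Guild precedence AOA > AOB > NOB**: some species carry both ammonia-
  and nitrite-oxidation genes, and any partition needs a rule. Ammonia
  oxidation takes precedence and dual-evidence species are flagged instead
  of hidden.
* **Ecosystems are processed independently** (separate tables, separate
  filters); only species *registries* are compared across ecosystems, by
  exact name. Name-based matching is fragile across annotation runs with
  different reference versions — no synonym resolution is attempted, and
  that is a stated limitation rather than a hidden heuristic.
* The command-line wrapper reads YAML generator configs; the pipeline's
  thresholds are all ordinary function arguments first, flags second.

## Problem sizes in the test suite

Unit and property tests run on tables of ≤ 60 records (where brute-force
recomputation over raw rows is feasible as an independent oracle, 200+
random cases), the two reference communities at full scale (5363 and 9117
species; ~19k and ~31k records), and recovery experiments at 500 species ×
19 samples × 20 seeds — sizes chosen so the whole suite exercises realistic
scales while completing in about a minute.

## Known limitations

* Presence/absence only: no RPKM/TPM weighting, so a single detected ORF
  counts as much as a hundred.
* Versatility is genomic potential, not activity — a species *encoding*
  denitrification genes need not denitrify.
* The guild rules trust the lineage's domain rank for the archaea/bacteria
  split and the annotation's species binomial for identity; ambiguous or
  unclassified hits are dropped at ingestion.
* The shipped ontology is a curated default, not an authority; serious use
  should load the mapping of the annotation database actually used.
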