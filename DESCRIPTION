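Package: nversa
Title: Nitrogen-Cycle Metabolic Versatility Profiling of Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies which microbial species encode which of the eight
    nitrogen-transformation pathways (ammonia assimilation, assimilatory
    nitrate reduction, dissimilatory nitrate to nitrite, dissimilatory
    nitrite to ammonia, denitrification, nitrification, nitrogen fixation,
    anammox) from per-sample gene-family annotation tables of the kind
    produced by searching assembled metagenomic ORFs against a curated
    nitrogen-cycle gene database. Quantifies multi-pathway ("versatile")
    species, enumerates exact pathway combinations (UpSet semantics),
    profiles nitrifier (AOA/AOB/NOB) and nitrogen-fixer guilds, compares
    species registries across ecosystems, and ships a synthetic-community
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
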