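# Deterministic "exact marginal" community builders.
#
# These construct noiseless annotation tables whose downstream statistics
# are known by construction: every species appears in exactly 2 of 3
# samples (so the default prevalence filter keeps all of them) and carries
# exactly one marker gene per encoded pathway (plus guild-defining genes
# where a guild identity is required). They realize the printed marginal
# counts of the soil and marine reference analyses and are used by the
# worked-example tests; they are synthetic stand-ins, not the study data.

.REP_GENE <- c(
  AMMONIA_ASSIMILATION      = "glnA",
  ASSIM_NITRATE_REDUCTION   = "nasA",
  DISSIM_NITRATE_TO_NITRITE = "narG",
  DISSIM_NITRITE_TO_AMMONIA = "nirB",
  DENITRIFICATION           = "nirK",
  NITRIFICATION             = "amoA",
  NITROGEN_FIXATION         = "nifH",
  ANAMMOX                   = "hzsA"
)

gene_block <- function(n, genes) {
  tibble::tibble(genes = rep(list(genes), n))
}

# accompanying pathway codes -> gene vector, plus an explicit defining gene
combo_genes <- function(paths, defining_gene = NULL) {
  c(defining_gene, unname(.REP_GENE[paths]))
}

#' Build an annotation table from explicit species blocks
#'
#' Each row of `blocks` describes one species: a `genes` list-column plus
#' lineage columns (`domain`, `phylum`, `class`, `genus`; any absent column
#' defaults to empty). Every species is placed, noiselessly, in 2 of
#' `n_samples` samples (rotating pairs), one record per gene per occupied
#' sample.
#'
#' @param blocks tibble with list-column `genes` and optional lineage
#'   columns; one row per species. A `species` column may be supplied;
#'   otherwise names are generated from `species_prefix`.
#' @param ecosystem label for the table.
#' @param species_prefix prefix for generated species names.
#' @param n_samples number of samples (>= 2).
#' @return an `annotation_table`.
#' @export
community_from_blocks <- function(blocks, ecosystem = "synthetic",
                                  species_prefix = "sp", n_samples = 3) {
  stopifnot(n_samples >= 2)
  n <- nrow(blocks)
  if (!"species" %in% names(blocks)) {
    blocks$species <- sprintf("%s_%05d", species_prefix, seq_len(n))
  }
  for (col in c("domain", "phylum", "class", "genus")) {
    if (!col %in% names(blocks)) blocks[[col]] <- ""
  }
  samples <- sprintf("s%02d", seq_len(n_samples))
  pairs <- utils::combn(n_samples, 2)
  pick <- ((seq_len(n) - 1) %% ncol(pairs)) + 1
  s1 <- samples[pairs[1, pick]]
  s2 <- samples[pairs[2, pick]]
  len <- lengths(blocks$genes)
  idx <- rep(seq_len(n), times = len)   # per-gene species index
  gene_vec <- unlist(blocks$genes, use.names = FALSE)
  one <- tibble::tibble(
    gene = gene_vec,
    domain = blocks$domain[idx], phylum = blocks$phylum[idx],
    class = blocks$class[idx], order = "", family = "",
    genus = blocks$genus[idx], species = blocks$species[idx], count = 1L)
  recs <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(sample_id = s1[idx]), one),
    dplyr::bind_cols(tibble::tibble(sample_id = s2[idx]), one))
  annotation_table(recs, ecosystem)
}

# Assign lineages so that the versatile pool has a prescribed taxonomic
# composition; `major` is a tibble (domain, phylum, class, n) consumed in
# order by non-archaeal versatile species; everything else cycles `filler`.
assign_fixture_taxa <- function(blocks, major, filler) {
  n <- nrow(blocks)
  blocks$domain <- ifelse(blocks$archaeal, "Archaea", "Bacteria")
  blocks$phylum <- ifelse(blocks$archaeal, "Thaumarchaeota", "")
  blocks$class <- ""
  slots <- which(blocks$versatile & !blocks$archaeal)
  stopifnot(sum(major$n) <= length(slots))
  pos <- 1
  for (j in seq_len(nrow(major))) {
    idx <- slots[pos:(pos + major$n[j] - 1)]
    blocks$phylum[idx] <- major$phylum[j]
    blocks$class[idx] <- major$class[j]
    blocks$domain[idx] <- major$domain[j]
    pos <- pos + major$n[j]
  }
  rest <- c(slots[pos:length(slots)],
            which(!blocks$versatile & !blocks$archaeal))
  fi <- ((seq_along(rest) - 1) %% nrow(filler)) + 1
  blocks$phylum[rest] <- filler$phylum[fi]
  blocks$class[rest] <- filler$class[fi]
  blocks$domain[rest] <- filler$domain[fi]
  # genus: groups of 4 species within each (phylum, class) stratum
  key <- paste(blocks$phylum, blocks$class, sep = "/")
  blocks$genus <- ""
  for (k in unique(key)) {
    idx <- which(key == k)
    blocks$genus[idx] <- sprintf("%s_g%04d", substr(gsub("[^A-Za-z]", "", k), 1, 5),
                                 ceiling(seq_along(idx) / 4))
  }
  blocks
}

.FILLER_TAXA <- tibble::tibble(
  domain = "Bacteria",
  phylum = c("Firmicutes", "Bacteroidetes", "Chloroflexi", "Acidobacteria",
             "Gemmatimonadetes", "Planctomycetes", "Verrucomicrobia",
             "Proteobacteria", "Proteobacteria", "Nitrospirae"),
  class = c("", "", "", "", "", "", "",
            "Gammaproteobacteria", "Deltaproteobacteria", "")
)

#' Soil reference community (exact marginal mode)
#'
#' A deterministic, noiseless annotation table realizing the printed
#' marginals of the soil reference analysis: 5363 nitrogen-transforming
#' species of which 2065 are versatile (degree counts 3298, 1021, 490, 292,
#' 201, 46, 14, 1 for degrees 1-8); 147 nitrifiers partitioned into 13 AOA
#' (2 pure), 99 AOB (12 pure) and 35 NOB (2 pure); 106 nitrogen fixers (15
#' pure); top versatile combinations ammonia assimilation + assimilatory
#' nitrate reduction (337 species) and ammonia assimilation + dissimilatory
#' nitrite to ammonia (215); versatile pool dominated by Actinobacteria
#' (496), Alphaproteobacteria (310) and Betaproteobacteria (289).
#'
#' @return an `annotation_table` labeled `"soil"`.
#' @export
soil_reference_fixture <- function() {
  deg6 <- c("AMMONIA_ASSIMILATION", "ASSIM_NITRATE_REDUCTION",
            "DISSIM_NITRATE_TO_NITRITE", "DISSIM_NITRITE_TO_AMMONIA",
            "DENITRIFICATION")
  blocks <- dplyr::bind_rows(
    # --- AOA: 13 archaeal amoA carriers, 2 pure ---
    gene_block(2, "amoA"),
    gene_block(4, combo_genes(deg6, "amoA")),
    gene_block(3, c("amoA", "glnA")),
    gene_block(2, c("amoA", "nirK")),
    gene_block(2, c("amoA", "glnA", "nirB")),
    # --- AOB: 99 bacterial amo/hao carriers, 12 pure ---
    gene_block(6, "amoA"),
    gene_block(6, "hao"),
    gene_block(14, combo_genes(deg6, "amoA")),
    gene_block(7, combo_genes(c(deg6, "ANAMMOX"), "amoA")),
    gene_block(1, c(combo_genes(c(deg6, "ANAMMOX"), "amoA"), "nifH")),
    gene_block(13, c("amoA", "glnA")),
    gene_block(13, c("hao", "nirB")),
    gene_block(13, c("amoA", "nirK")),
    gene_block(13, c("amoA", "glnA", "nasA")),
    gene_block(13, c("amoA", "glnA", "nirK")),
    # --- NOB: 35 bacterial nxrA carriers (no amo/hao), 2 pure ---
    gene_block(2, "nxrA"),
    gene_block(12, combo_genes(deg6, "nxrA")),
    gene_block(9, c("nxrA", "nasA")),
    gene_block(7, c("nxrA", "nasA", "nirB")),
    gene_block(5, c("nxrA", "glnA", "nasA", "nirB")),
    # --- nitrogen fixers: 105 nifH carriers here (+1 AOB above) = 106 ---
    gene_block(15, "nifH"),
    gene_block(16, combo_genes(deg6, "nifH")),
    gene_block(10, c("nifH", "glnA")),
    gene_block(7, combo_genes(c(deg6, "ANAMMOX"), "nifH")),
    gene_block(9, c("nifH", "nirK")),
    gene_block(9, c("nifH", "nirB")),
    gene_block(9, c("nifH", "nasA")),
    gene_block(9, c("nifH", "glnA", "nirK")),
    gene_block(9, c("nifH", "glnA", "nasA")),
    gene_block(9, c("nifH", "glnA", "nirB")),
    gene_block(3, c("nifH", "glnA", "nasA", "nirK")),
    # --- non-guild versatile species ---
    gene_block(337, c("glnA", "nasA")),
    gene_block(215, c("glnA", "nirB")),
    gene_block(130, c("glnA", "nirK")),
    gene_block(130, c("glnA", "narG")),
    gene_block(119, c("nasA", "narG")),
    gene_block(214, c("glnA", "nasA", "narG")),
    gene_block(214, c("glnA", "nasA", "nirB")),
    gene_block(142, c("glnA", "nasA", "narG", "nirB")),
    gene_block(142, c("glnA", "nasA", "narG", "nirK")),
    gene_block(201, c("glnA", "nasA", "narG", "nirB", "nirK")),
    # --- single-pathway species ---
    gene_block(1200, "glnA"),
    gene_block(600, "nasA"),
    gene_block(500, "narG"),
    gene_block(400, "nirB"),
    gene_block(400, "nirK"),
    gene_block(167, "hzsA")
  )
  blocks$archaeal <- c(rep(TRUE, 13), rep(FALSE, nrow(blocks) - 13))
  blocks$versatile <- lengths(blocks$genes) >= 2
  major <- tibble::tibble(
    domain = "Bacteria",
    phylum = c("Actinobacteria", "Proteobacteria", "Proteobacteria"),
    class = c("", "Alphaproteobacteria", "Betaproteobacteria"),
    n = c(496L, 310L, 289L))
  blocks <- assign_fixture_taxa(blocks, major, .FILLER_TAXA)
  blocks$species <- sprintf("soil_sp_%05d", seq_len(nrow(blocks)))
  community_from_blocks(blocks, ecosystem = "soil")
}

#' Marine reference community (exact marginal mode)
#'
#' Deterministic noiseless table realizing the marine marginals: 9117
#' species, degree counts 5915, 1630, 725, 444, 291, 90, 14, 8 (3202
#' versatile, 35%), versatile pool dominated by Alphaproteobacteria (897),
#' Gammaproteobacteria (736) and Bacteroidetes (288), and 2462 species
#' shared by name with [soil_reference_fixture()] (so 73% of marine species
#' are absent from soil). Multi-pathway repertoires follow canonical
#' pathway order.
#'
#' @return an `annotation_table` labeled `"marine"`.
#' @export
marine_reference_fixture <- function() {
  codes <- n_pathways()
  prefix_genes <- function(k) unname(.REP_GENE[codes[seq_len(k)]])
  deg_counts <- c(5915L, 1630L, 725L, 444L, 291L, 90L, 14L, 8L)
  blocks <- dplyr::bind_rows(
    gene_block(2000, "glnA"),
    gene_block(1200, "nasA"),
    gene_block(900, "narG"),
    gene_block(700, "nirB"),
    gene_block(600, "nirK"),
    gene_block(515, "hzsA"),
    dplyr::bind_rows(lapply(2:8, function(k) {
      gene_block(deg_counts[k], prefix_genes(k))
    }))
  )
  blocks$archaeal <- FALSE
  blocks$versatile <- lengths(blocks$genes) >= 2
  major <- tibble::tibble(
    domain = "Bacteria",
    phylum = c("Proteobacteria", "Proteobacteria", "Bacteroidetes"),
    class = c("Alphaproteobacteria", "Gammaproteobacteria", ""),
    n = c(897L, 736L, 288L))
  filler <- .FILLER_TAXA[.FILLER_TAXA$phylum != "Bacteroidetes" &
                           .FILLER_TAXA$class != "Gammaproteobacteria", ]
  blocks <- assign_fixture_taxa(blocks, major, filler)
  n <- nrow(blocks)
  n_shared <- 2462L
  blocks$species <- c(sprintf("soil_sp_%05d", seq_len(n_shared)),
                      sprintf("marine_sp_%05d", seq_len(n - n_shared)))
  community_from_blocks(blocks, ecosystem = "marine")
}
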