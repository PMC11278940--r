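# Independent brute-force oracles: plain loops over raw record rows, using
# only the shipped gene->pathway TSV read with base R. Nothing here calls
# the package's profiling/guild code paths.

oracle_gene_map <- local({
  f <- system.file("extdata", "pathway_map.tsv", package = "nversa")
  d <- utils::read.delim(f, comment.char = "#", stringsAsFactors = FALSE)
  split(d$pathway, tolower(d$gene_family))
})

ORACLE_PATHWAY_ORDER <- c(
  "AMMONIA_ASSIMILATION", "ASSIM_NITRATE_REDUCTION",
  "DISSIM_NITRATE_TO_NITRITE", "DISSIM_NITRITE_TO_AMMONIA",
  "DENITRIFICATION", "NITRIFICATION", "NITROGEN_FIXATION", "ANAMMOX")

# records: data.frame with sample_id, gene, domain, species (raw rows)
oracle_prevalence <- function(records) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    sp <- records$species[i]
    out[[sp]] <- union(out[[sp]], records$sample_id[i])
  }
  vapply(out, length, integer(1))
}

oracle_species_pathways <- function(records, min_prevalence = 2) {
  prev <- oracle_prevalence(records)
  keep <- names(prev)[prev >= min_prevalence]
  sets <- list()
  for (i in seq_len(nrow(records))) {
    sp <- records$species[i]
    if (!sp %in% keep) next
    p <- oracle_gene_map[[tolower(records$gene[i])]]
    if (!is.null(p)) sets[[sp]] <- union(sets[[sp]], p)
  }
  if (length(sets) == 0) return(sets)
  sets[order(names(sets))]
}

oracle_degree_hist <- function(sets) {
  h <- integer(8)
  for (s in sets) h[length(s)] <- h[length(s)] + 1L
  names(h) <- as.character(1:8)
  h
}

oracle_combo_counts <- function(sets) {
  keys <- vapply(sets, function(s) {
    paste(ORACLE_PATHWAY_ORDER[ORACLE_PATHWAY_ORDER %in% s], collapse = "+")
  }, character(1))
  tab <- table(keys)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# guild tallies by direct enumeration of each species' gene set
oracle_guild_tally <- function(records, sets) {
  amo <- c("amoa", "amob", "amoc", "pmoa", "pmob", "pmoc", "hao")
  nxr <- c("nxra", "nxrb")
  nif <- c("nifh", "nifd", "nifk")
  genes <- list(); domain <- list()
  for (i in seq_len(nrow(records))) {
    sp <- records$species[i]
    if (!sp %in% names(sets)) next
    genes[[sp]] <- union(genes[[sp]], tolower(records$gene[i]))
    domain[[sp]] <- records$domain[i]
  }
  tally <- c(AOA = 0L, AOB = 0L, NOB = 0L, NFIXER = 0L)
  pure <- c(AOA = 0L, AOB = 0L, NOB = 0L, NFIXER = 0L)
  for (sp in names(genes)) {
    g <- genes[[sp]]
    lab <- NULL
    if (any(g %in% amo)) {
      lab <- if (identical(domain[[sp]], "Archaea")) "AOA" else "AOB"
    } else if (any(g %in% nxr)) {
      lab <- "NOB"
    }
    if (!is.null(lab)) {
      tally[lab] <- tally[lab] + 1L
      if (identical(sets[[sp]], "NITRIFICATION")) pure[lab] <- pure[lab] + 1L
    }
    if (any(g %in% nif)) {
      tally["NFIXER"] <- tally["NFIXER"] + 1L
      if (identical(sets[[sp]], "NITROGEN_FIXATION")) {
        pure["NFIXER"] <- pure["NFIXER"] + 1L
      }
    }
  }
  list(total = tally, pure = pure)
}

# Random raw annotation records drawing from builtin genes plus unknowns.
random_records <- function(seed, n_records = 50, n_species = 8,
                           n_samples = 4, unknown_frac = 0.1) {
  set.seed(seed)
  gene_pool <- c("amoA", "hao", "nxrA", "nxrB", "nifH", "nifD", "glnA",
                 "gltB", "nasA", "narG", "napA", "nirB", "nirK", "nosZ",
                 "hzsA", "ureC")
  if (unknown_frac > 0) gene_pool <- c(gene_pool, "mysteryX", "cryptic1")
  # genera are drawn first and carry their lineage, so a genus name never
  # spans two phyla (matching how real annotations nest)
  n_genera <- max(2, n_species %/% 2)
  gen_domain <- sample(c("Bacteria", "Archaea"), n_genera, replace = TRUE,
                       prob = c(0.8, 0.2))
  gen_phylum <- ifelse(gen_domain == "Archaea", "Thaumarchaeota",
                       sample(c("Actinobacteria", "Proteobacteria",
                                "Firmicutes"), n_genera, replace = TRUE))
  gen_class <- ifelse(gen_phylum == "Proteobacteria", "Alphaproteobacteria", "")
  gidx <- sample.int(n_genera, n_species, replace = TRUE)
  sp_domain <- gen_domain[gidx]
  sp_phylum <- gen_phylum[gidx]
  sp_class <- gen_class[gidx]
  sp_genus <- sprintf("g%02d", gidx)
  idx <- sample.int(n_species, n_records, replace = TRUE)
  data.frame(
    sample_id = sprintf("s%d", sample.int(n_samples, n_records, replace = TRUE)),
    gene = sample(gene_pool, n_records, replace = TRUE),
    domain = sp_domain[idx], phylum = sp_phylum[idx], class = sp_class[idx],
    order = "", family = "", genus = sp_genus[idx],
    species = sprintf("sp%02d", idx),
    count = 1L,
    stringsAsFactors = FALSE)
}

profile_sets_from <- function(profiles) {
  codes <- n_pathways()
  m <- as.matrix(profiles[, codes])
  sets <- lapply(seq_len(nrow(m)), function(i) codes[m[i, ]])
  names(sets) <- profiles$taxon
  sets[order(names(sets))]
}
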