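# Nitrifier subgroup and nitrogen-fixer classification.

guild_table <- function(rows) {
  recs <- do.call(rbind, lapply(rows, function(r) {
    ng <- length(r$genes)
    data.frame(
      sample_id = rep(c("s1", "s2"), each = ng),
      gene = rep(r$genes, 2),
      domain = r$domain,
      phylum = if (is.null(r$phylum)) "Proteobacteria" else r$phylum,
      class = if (is.null(r$class)) "Betaproteobacteria" else r$class,
      order = "", family = "",
      genus = if (is.null(r$genus)) "g1" else r$genus,
      species = r$species, count = 1L, stringsAsFactors = FALSE)
  }))
  annotation_table(recs, "guild-test")
}

test_that("guild precedence: AOA > AOB > NOB, with nitrogen fixation as a flag", {
  tab <- guild_table(list(
    list(species = "arch sp", domain = "Archaea", phylum = "Thaumarchaeota",
         class = "", genes = c("amoA", "narG")),
    list(species = "hao sp", domain = "Bacteria", genes = "hao"),
    list(species = "comammox sp", domain = "Bacteria",
         genes = c("amoA", "nxrB")),
    list(species = "nob sp", domain = "Bacteria", genes = c("nxrA", "glnA")),
    list(species = "fixer sp", domain = "Bacteria", genes = c("nifH", "nxrA")),
    list(species = "plain sp", domain = "Bacteria", genes = "glnA")))
  prof <- build_profiles(tab, REF_ONTOLOGY, "species")
  a <- assign_guilds(tab, prof)
  g <- stats::setNames(a$guild, a$species)
  expect_identical(unname(g["arch sp"]), "AOA")
  expect_identical(unname(g["hao sp"]), "AOB")
  expect_identical(unname(g["comammox sp"]), "AOB")  # precedence over NOB
  expect_true(a$dual_evidence[a$species == "comammox sp"])
  expect_identical(unname(g["nob sp"]), "NOB")
  expect_identical(unname(g["fixer sp"]), "NOB")  # nitrifier label kept
  expect_true(a$nfixer[a$species == "fixer sp"])
  expect_identical(unname(g["plain sp"]), "NONE")
})

test_that("pmo-only ammonia oxidizers are flagged as putative methanotroph cross-hits", {
  tab <- guild_table(list(
    list(species = "pmo sp", domain = "Bacteria", genes = c("pmoA", "glnA")),
    list(species = "amo sp", domain = "Bacteria", genes = c("amoA", "pmoB"))))
  prof <- build_profiles(tab, REF_ONTOLOGY, "species")
  a <- assign_guilds(tab, prof)
  expect_true(a$pmo_only[a$species == "pmo sp"])
  expect_false(a$pmo_only[a$species == "amo sp"])
  expect_identical(a$guild, c("AOB", "AOB"))
})

test_that("guild summaries count pure members by profile degree", {
  # 3 AOA: one pure, two versatile
  tab <- guild_table(list(
    list(species = "aoa1", domain = "Archaea", phylum = "Thaumarchaeota",
         class = "", genes = "amoA"),
    list(species = "aoa2", domain = "Archaea", phylum = "Thaumarchaeota",
         class = "", genes = c("amoA", "glnA")),
    list(species = "aoa3", domain = "Archaea", phylum = "Thaumarchaeota",
         class = "", genes = c("amoB", "nirK", "glnA"))))
  prof <- build_profiles(tab, REF_ONTOLOGY, "species")
  a <- assign_guilds(tab, prof)
  s <- guild_summary(a, prof, "AOA")
  expect_identical(s$n_total, 3L)
  expect_identical(s$n_pure, 1L)
  expect_identical(s$n_pure + s$n_versatile, s$n_total)
  expect_identical(s$percent_versatile, 67L)
  top <- s$top_combinations
  expect_identical(top$accompanying[1], "AMMONIA_ASSIMILATION")
  # empty guild: zeros, no error
  z <- guild_summary(a, prof, "NFIXER")
  expect_identical(z$n_total, 0L)
  expect_identical(z$percent_versatile, 0L)
})

test_that("guild summaries are invariant to record order", {
  recs <- random_records(99, n_records = 60, n_species = 12)
  t1 <- annotation_table(recs, "x")
  t2 <- annotation_table(recs[sample.int(nrow(recs)), ], "x")
  p1 <- build_profiles(apply_prevalence_filter(t1), REF_ONTOLOGY, "species")
  p2 <- build_profiles(apply_prevalence_filter(t2), REF_ONTOLOGY, "species")
  a1 <- suppressWarnings(assign_guilds(apply_prevalence_filter(t1), p1))
  a2 <- suppressWarnings(assign_guilds(apply_prevalence_filter(t2), p2))
  for (g in c("AOA", "AOB", "NOB", "NFIXER")) {
    s1 <- guild_summary(a1, p1, g)
    s2 <- guild_summary(a2, p2, g)
    expect_identical(s1[c("n_total", "n_pure", "n_versatile")],
                     s2[c("n_total", "n_pure", "n_versatile")])
  }
})

test_that("guild tallies match direct enumeration on random tables", {
  for (seed in 41:55) {
    recs <- random_records(seed, n_records = 50, n_species = 10)
    tab <- annotation_table(recs, "fuzz")
    osets <- oracle_species_pathways(recs)
    if (length(osets) == 0) next
    filt <- apply_prevalence_filter(tab)
    prof <- build_profiles(filt, REF_ONTOLOGY, "species")
    a <- suppressWarnings(assign_guilds(filt, prof))
    o <- oracle_guild_tally(recs[recs$species %in% prof$taxon, ], osets)
    for (g in c("AOA", "AOB", "NOB", "NFIXER")) {
      s <- guild_summary(a, prof, g)
      expect_identical(s$n_total, unname(o$total[g]))
      expect_identical(s$n_pure, unname(o$pure[g]))
    }
    # partition: AOA + AOB + NOB = all species with nitrification evidence
    n_nitrifiers <- sum(vapply(profile_sets_from(prof),
                               function(s) "NITRIFICATION" %in% s, logical(1)))
    s3 <- sum(a$guild %in% c("AOA", "AOB", "NOB"))
    expect_identical(s3, n_nitrifiers)
    # every guild member encodes its defining pathway
    for (g in c("AOA", "AOB", "NOB")) {
      members <- a$species[a$guild == g]
      expect_true(all(prof$NITRIFICATION[match(members, prof$taxon)]))
    }
    expect_true(all(prof$NITROGEN_FIXATION[match(a$species[a$nfixer],
                                                 prof$taxon)]))
  }
})

test_that("heatmap matrices carry degrees in row sums and a taxon annotation", {
  tab <- guild_table(list(
    list(species = "fx1", domain = "Bacteria", phylum = "Proteobacteria",
         class = "Alphaproteobacteria", genes = "nifH"),
    list(species = "fx2", domain = "Bacteria", phylum = "Proteobacteria",
         class = "Alphaproteobacteria", genes = c("nifH", "glnA", "nosZ"))))
  prof <- build_profiles(tab, REF_ONTOLOGY, "species")
  a <- assign_guilds(tab, prof)
  m <- heatmap_matrix(a, prof, "NFIXER")
  expect_identical(dim(m), c(2L, 8L))
  expect_identical(unname(rowSums(m)[order(rownames(m))]),
                   as.numeric(prof$degree[order(prof$taxon)]))
  expect_length(attr(m, "taxon_annotation"), 2L)
  # a pure fixer's row has its single 1 in the nitrogen-fixation column
  expect_identical(unname(m["fx1", "NITROGEN_FIXATION"]), 1L)
  expect_identical(sum(m["fx1", ]), 1L)
})
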