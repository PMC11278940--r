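# Prevalence filtering, pathway profiles, versatility statistics.

test_that("sample prevalence counts distinct samples per species", {
  tab <- tiny_table()
  prev <- species_sample_prevalence(tab)
  expect_identical(prev$n_samples[prev$species == "sp A"], 2L)
  expect_identical(prev$n_samples[prev$species == "sp B"], 2L)
  expect_identical(prev$n_samples[prev$species == "sp C"], 1L)
})

test_that("prevalence filter keeps only multi-sample species", {
  tab <- tiny_table()
  filt <- apply_prevalence_filter(tab)
  expect_setequal(unique(filt$species), c("sp A", "sp B"))
  # min_prevalence = 1 is the identity
  expect_identical(tibble::as_tibble(apply_prevalence_filter(tab, 1)),
                   tibble::as_tibble(tab))
  expect_error(apply_prevalence_filter(tab, 0), "min_prevalence")
})

test_that("species profiles union evidence across samples; unmapped-only species drop", {
  recs <- data.frame(
    sample_id = c("s1", "s2", "s2", "s1", "s2"),
    gene = c("amoA", "glnA", "glnA", "weirdX", "weirdX"),
    domain = "Bacteria", phylum = "Actinobacteria", class = "",
    order = "", family = "", genus = c("g1", "g1", "g1", "g2", "g2"),
    species = c("sp X", "sp X", "sp X", "sp Y", "sp Y"),
    count = 1L, stringsAsFactors = FALSE)
  tab <- apply_prevalence_filter(annotation_table(recs, "t"))
  prof <- build_profiles(tab, REF_ONTOLOGY, "species")
  expect_identical(prof$taxon, "sp X")  # sp Y has only unmapped genes
  expect_true(prof$NITRIFICATION && prof$AMMONIA_ASSIMILATION)
  expect_identical(prof$degree, 2L)
  expect_warning(build_profiles(tab, REF_ONTOLOGY, "species",
                                warn_unknown = TRUE), "weirdX")
})

test_that("genus profiles are the union of member species", {
  recs <- data.frame(
    sample_id = rep(c("s1", "s2"), 2),
    gene = c("amoA", "amoA", "nifH", "nifH"),
    domain = "Bacteria", phylum = "Proteobacteria",
    class = "Alphaproteobacteria", order = "", family = "",
    genus = "SharedGenus",
    species = c("sp one", "sp one", "sp two", "sp two"),
    count = 1L, stringsAsFactors = FALSE)
  tab <- apply_prevalence_filter(annotation_table(recs, "t"))
  ge <- build_profiles(tab, REF_ONTOLOGY, "genus")
  expect_identical(nrow(ge), 1L)
  expect_identical(ge$degree, 2L)  # union of two degree-1 species
  expect_true(ge$NITRIFICATION && ge$NITROGEN_FIXATION)
})

test_that("degree distribution and versatile fraction follow the definitions", {
  # printed marine per-degree counts as a direct input
  marine_counts <- c(5915L, 1630L, 725L, 444L, 291L, 90L, 14L, 8L)
  prof <- tibble::tibble(degree = rep(1:8, marine_counts))
  dist <- degree_distribution(prof)
  expect_identical(unname(dist$counts), marine_counts)
  expect_identical(dist$versatile_total, 3202L)
  vf <- versatile_fraction(dist)
  expect_identical(vf$count, 3202L)
  expect_identical(vf$percent_display, 35L)
  # all-singleton edge case
  ones <- degree_distribution(tibble::tibble(degree = rep(1L, 5)))
  expect_identical(versatile_fraction(ones)$count, 0L)
  expect_error(versatile_fraction(degree_distribution(tibble::tibble(degree = integer()))),
               "empty")
})

test_that("combination counts use exact-set (distinct) semantics", {
  recs <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 4),
    gene = rep(c("glnA", "glnA", "glnA", "nasA"), 2),
    domain = "Bacteria", phylum = "Actinobacteria", class = "",
    order = "", family = "", genus = "g",
    species = rep(c("a sp", "b sp", "c sp", "c sp"), 2),
    count = 1L, stringsAsFactors = FALSE)
  prof <- build_profiles(apply_prevalence_filter(annotation_table(recs, "t")),
                         REF_ONTOLOGY, "species")
  cc <- combination_counts(prof)
  expect_identical(cc$n[cc$combo == "AMMONIA_ASSIMILATION"], 2L)
  expect_identical(
    cc$n[cc$combo == "AMMONIA_ASSIMILATION+ASSIM_NITRATE_REDUCTION"], 1L)
  expect_identical(sum(cc$n), nrow(prof))
})

test_that("taxonomic composition groups rare labels into Other", {
  prof <- tibble::tibble(
    taxon = sprintf("sp%d", 1:4),
    domain = "Bacteria",
    phylum = c("Actinobacteria", "Actinobacteria", "Proteobacteria", "Weirdota"),
    class = c("", "", "Alphaproteobacteria", ""),
    order = "", family = "", genus = "", species = "",
    degree = c(2L, 2L, 2L, 2L))
  tc <- taxonomic_composition(prof, versatile_only = TRUE)
  expect_identical(tc$percent_display[tc$display_taxon == "Actinobacteria"], 50L)
  # singleton labels merged
  expect_true("Other" %in% tc$display_taxon)
  expect_identical(sum(tc$n), 4L)
  none <- taxonomic_composition(prof[prof$degree > 2, ], versatile_only = TRUE)
  expect_identical(nrow(none), 0L)
})

test_that("profile statistics match brute-force recomputation on random tables", {
  for (seed in 1:25) {
    recs <- random_records(seed, n_records = sample(10:50, 1))
    tab <- annotation_table(recs, "fuzz")
    # prevalence oracle
    prev <- species_sample_prevalence(tab)
    oprev <- oracle_prevalence(recs)
    expect_identical(prev$n_samples[match(names(oprev), prev$species)],
                     unname(oprev))
    osets <- oracle_species_pathways(recs)
    if (length(osets) == 0) next
    prof <- build_profiles(apply_prevalence_filter(tab), REF_ONTOLOGY,
                           "species")
    expect_identical(lapply(profile_sets_from(prof), sort),
                     lapply(osets, sort))
    dist <- degree_distribution(prof)
    expect_identical(unname(dist$counts), unname(oracle_degree_hist(osets)))
    cc <- combination_counts(prof)
    occ <- oracle_combo_counts(osets)
    expect_identical(occ[sort(names(occ))],
                     stats::setNames(cc$n, cc$combo)[sort(names(occ))])
  }
})

test_that("conservation and monotonicity invariants hold on fuzzed tables", {
  for (seed in 26:40) {
    recs <- random_records(seed, n_records = 60, n_species = 10)
    tab <- annotation_table(recs, "fuzz")
    filt2 <- try(apply_prevalence_filter(tab, 2), silent = TRUE)
    if (inherits(filt2, "try-error")) next
    prof2 <- build_profiles(filt2, REF_ONTOLOGY, "species")
    # conservation: degree histogram and combination counts partition the set
    expect_identical(degree_distribution(prof2)$total, nrow(prof2))
    expect_identical(sum(combination_counts(prof2)$n), nrow(prof2))
    # filter monotonicity: stricter prevalence never enlarges the set
    filt3 <- try(apply_prevalence_filter(tab, 3), silent = TRUE)
    if (!inherits(filt3, "try-error")) {
      prof3 <- build_profiles(filt3, REF_ONTOLOGY, "species")
      expect_lte(nrow(prof3), nrow(prof2))
      shared <- intersect(prof3$taxon, prof2$taxon)
      expect_true(all(prof3$degree[match(shared, prof3$taxon)] ==
                        prof2$degree[match(shared, prof2$taxon)]))
    }
    # annotation monotonicity: adding records never lowers a degree
    extra <- recs[1, ]
    extra$gene <- "hzsA"; extra$sample_id <- "s1"
    tab_plus <- annotation_table(rbind(recs, extra), "fuzz")
    prof_plus <- build_profiles(apply_prevalence_filter(tab_plus, 2),
                                REF_ONTOLOGY, "species")
    shared <- intersect(prof2$taxon, prof_plus$taxon)
    expect_true(all(prof_plus$degree[match(shared, prof_plus$taxon)] >=
                      prof2$degree[match(shared, prof2$taxon)]))
    # genus consistency: genera holding a versatile species are versatile
    gen <- build_profiles(filt2, REF_ONTOLOGY, "genus")
    sp_versatile_genera <- unique(prof2$genus[prof2$degree >= 2 &
                                                prof2$genus != ""])
    expect_true(all(gen$degree[gen$taxon %in% sp_versatile_genera] >= 2))
    # genus degree >= max member species degree
    for (g in unique(prof2$genus[prof2$genus != ""])) {
      if (g %in% gen$taxon) {
        expect_gte(gen$degree[gen$taxon == g][1],
                   max(prof2$degree[prof2$genus == g]))
      }
    }
  }
})
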