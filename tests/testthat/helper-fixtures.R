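# Shared fixtures, built once per test run.

REF_SOIL <- soil_reference_fixture()
REF_MARINE <- marine_reference_fixture()
REF_ONTOLOGY <- load_pathway_ontology()

soil_species_profiles <- function() {
  build_profiles(apply_prevalence_filter(REF_SOIL), REF_ONTOLOGY, "species")
}

# tiny hand-checkable community: 3 species across 3 samples
tiny_table <- function() {
  recs <- data.frame(
    sample_id = c("s1", "s2", "s1", "s2", "s3", "s1"),
    gene = c("amoA", "amoA", "glnA", "nifH", "nifH", "nosZ"),
    domain = "Bacteria", phylum = "Proteobacteria",
    class = "Betaproteobacteria", order = "", family = "",
    genus = c("gA", "gA", "gA", "gB", "gB", "gC"),
    species = c("sp A", "sp A", "sp A", "sp B", "sp B", "sp C"),
    count = 1L, stringsAsFactors = FALSE)
  annotation_table(recs, "tiny")
}
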