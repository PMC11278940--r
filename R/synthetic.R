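# Synthetic community generator with known ground truth.
#
# Emulates the tabular structure of a nitrogen-cycle annotation run:
# species with pathway repertoires, several marker genes per pathway,
# per-sample occupancy, and per-gene detection noise. Counts are not
# modeled beyond presence (the downstream pipeline is presence/absence).

.DEFAULT_TAXA <- tibble::tibble(
  domain = c(rep("Bacteria", 9), "Archaea"),
  phylum = c("Actinobacteria", "Proteobacteria", "Proteobacteria",
             "Proteobacteria", "Firmicutes", "Bacteroidetes",
             "Acidobacteria", "Chloroflexi", "Nitrospirae",
             "Thaumarchaeota"),
  class = c("", "Alphaproteobacteria", "Betaproteobacteria",
            "Gammaproteobacteria", "", "", "", "", "", ""),
  weight = c(0.20, 0.15, 0.12, 0.08, 0.12, 0.10, 0.08, 0.07, 0.04, 0.04)
)

#' Configuration for the synthetic community generator
#'
#' Defaults emulate a soil-like nitrogen-transforming community: a skewed
#' per-pathway repertoire (ammonia assimilation common, anammox rare, mean
#' degree well below 2 so most species encode a single pathway), moderate
#' per-species sample occupancy (`psi ~ Beta(2, 2)`), and near-complete
#' per-gene detection.
#'
#' @param n_species number of species to simulate.
#' @param n_samples number of samples.
#' @param taxon_weights tibble with columns `domain`, `phylum`, `class`,
#'   `weight` (normalized internally).
#' @param repertoire_model either `"inclusion"` (independent per-pathway
#'   Bernoulli draws conditioned on a non-empty repertoire, using
#'   `inclusion_probs`) or a tibble with list-column `pathways` and column
#'   `prob` giving an explicit distribution over repertoires.
#' @param inclusion_probs named numeric vector over the 8 pathway codes.
#' @param genes_per_pathway integer range `c(min, max)`: how many marker
#'   genes of each owned pathway the species genome carries.
#' @param occupancy_alpha,occupancy_beta Beta parameters for per-species
#'   occupancy probability psi.
#' @param detection_prob probability delta in (0, 1] that an owned gene is
#'   detected in an occupied sample.
#' @param seed integer RNG seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_species = 500,
                             n_samples = 19,
                             taxon_weights = .DEFAULT_TAXA,
                             repertoire_model = "inclusion",
                             inclusion_probs = c(
                               AMMONIA_ASSIMILATION = 0.45,
                               ASSIM_NITRATE_REDUCTION = 0.20,
                               DISSIM_NITRATE_TO_NITRITE = 0.15,
                               DISSIM_NITRITE_TO_AMMONIA = 0.15,
                               DENITRIFICATION = 0.12,
                               NITRIFICATION = 0.04,
                               NITROGEN_FIXATION = 0.03,
                               ANAMMOX = 0.01),
                             genes_per_pathway = c(1, 3),
                             occupancy_alpha = 2,
                             occupancy_beta = 2,
                             detection_prob = 1,
                             seed = 1L) {
  if (n_samples < 1) abort_stage("n_samples must be >= 1")
  if (detection_prob <= 0 || detection_prob > 1) {
    abort_stage("detection_prob must be in (0, 1]")
  }
  if (is.character(repertoire_model)) {
    if (!setequal(names(inclusion_probs), n_pathways())) {
      abort_stage("inclusion_probs must be named by the 8 pathway codes")
    }
    if (all(inclusion_probs <= 0)) {
      abort_stage("repertoire model can only emit the empty set: all inclusion probabilities are zero")
    }
  } else {
    if (any(lengths(repertoire_model$pathways) == 0)) {
      abort_stage("explicit repertoire model contains the empty pathway set")
    }
    if (any(repertoire_model$prob < 0) || sum(repertoire_model$prob) <= 0) {
      abort_stage("explicit repertoire probabilities must be non-negative and sum > 0")
    }
  }
  tw <- taxon_weights
  tw$weight <- tw$weight / sum(tw$weight)
  structure(
    list(n_species = as.integer(n_species), n_samples = as.integer(n_samples),
         taxon_weights = tw, repertoire_model = repertoire_model,
         inclusion_probs = inclusion_probs[n_pathways()],
         genes_per_pathway = as.integer(genes_per_pathway),
         occupancy_alpha = occupancy_alpha, occupancy_beta = occupancy_beta,
         detection_prob = detection_prob, seed = as.integer(seed)),
    class = "generator_config"
  )
}

draw_repertoire <- function(config) {
  if (is.character(config$repertoire_model)) {
    p <- config$inclusion_probs
    repeat {
      keep <- stats::runif(8) < p
      if (any(keep)) return(n_pathways()[keep])
    }
  } else {
    m <- config$repertoire_model
    i <- sample.int(nrow(m), 1, prob = m$prob)
    m$pathways[[i]]
  }
}

#' Generate a synthetic annotation table with ground truth
#'
#' For each species: draw a taxon, a pathway repertoire, a gene set (1 to
#' `genes_per_pathway[2]` marker genes per owned pathway, sampled from the
#' ontology's genes of that pathway), an occupancy probability
#' `psi ~ Beta(alpha, beta)`, per-sample presence `Bernoulli(psi)`, and —
#' per occupied sample — each owned gene with probability `detection_prob`.
#' Species that emit zero records remain in the truth but are absent from
#' the table. Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @param ontology the ontology genes are drawn from.
#' @param ecosystem label for the emitted table.
#' @return list with `table` (an `annotation_table`) and `truth` (a tibble:
#'   `species`, lineage ranks, list-columns `pathways` and `genes`, `psi`,
#'   `occupied` sample-presence list-column, `degree`, `versatile`).
#' @export
generate_community <- function(config, ontology = load_pathway_ontology(),
                               ecosystem = "synthetic") {
  set.seed(config$seed)
  n <- config$n_species
  samples <- sprintf("s%02d", seq_len(config$n_samples))
  genes_by_pathway <- split(ontology$gene, ontology$pathway)

  ti <- sample.int(nrow(config$taxon_weights), n, replace = TRUE,
                   prob = config$taxon_weights$weight)
  tax <- config$taxon_weights[ti, c("domain", "phylum", "class")]
  genus_idx <- sample.int(max(1L, n %/% 4L), n, replace = TRUE)
  genus <- sprintf("%s_g%03d", substr(tax$phylum, 1, 4), genus_idx)
  species <- sprintf("syn_sp_%05d", seq_len(n))

  gpp <- config$genes_per_pathway
  paths_l <- vector("list", n)
  genes_l <- vector("list", n)
  occ_l <- vector("list", n)
  psi_v <- numeric(n)
  det_sample <- vector("list", n)
  det_gene <- vector("list", n)
  for (i in seq_len(n)) {
    paths <- draw_repertoire(config)
    genes <- unlist(lapply(paths, function(p) {
      pool <- genes_by_pathway[[p]]
      k <- if (gpp[1] == gpp[2]) gpp[1] else sample(seq(gpp[1], gpp[2]), 1)
      sample(pool, min(k, length(pool)))
    }), use.names = FALSE)
    psi <- stats::rbeta(1, config$occupancy_alpha, config$occupancy_beta)
    occ <- stats::runif(config$n_samples) < psi
    ds <- character(0); dg <- character(0)
    for (s in which(occ)) {
      hit <- genes[stats::runif(length(genes)) < config$detection_prob]
      if (length(hit)) {
        ds <- c(ds, rep(samples[s], length(hit)))
        dg <- c(dg, hit)
      }
    }
    paths_l[[i]] <- paths
    genes_l[[i]] <- sort(genes)
    occ_l[[i]] <- occ
    psi_v[i] <- psi
    det_sample[[i]] <- ds
    det_gene[[i]] <- dg
  }
  truth <- tibble::tibble(
    species = species, domain = tax$domain, phylum = tax$phylum,
    class = tax$class, genus = genus,
    pathways = paths_l, genes = genes_l, psi = psi_v, occupied = occ_l,
    degree = lengths(paths_l), versatile = lengths(paths_l) >= 2)
  nrec <- lengths(det_sample)
  idx <- rep(seq_len(n), times = nrec)
  if (length(idx) == 0) abort_stage("generated community emitted no records")
  recs <- tibble::tibble(
    sample_id = unlist(det_sample, use.names = FALSE),
    gene = unlist(det_gene, use.names = FALSE),
    domain = tax$domain[idx], phylum = tax$phylum[idx], class = tax$class[idx],
    order = "", family = "", genus = genus[idx], species = species[idx],
    count = 1L)
  list(table = annotation_table(recs, ecosystem), truth = truth)
}

#' Ground-truth recovery report
#'
#' Compares pipeline-recovered pathway profiles with the generator's truth,
#' restricted to species that survived the prevalence filter (i.e. appear in
#' `profiles`). Reports the exact-match rate of pathway sets, the mean
#' absolute error of the degree, and the bias of the recovered versatile
#' fraction (recovered minus truth, in percentage points, over the same
#' species).
#'
#' @param truth truth tibble from [generate_community()].
#' @param profiles species-level `profile_set` recovered by the pipeline.
#' @return list: `n_compared`, `exact_match_rate`, `degree_mae`,
#'   `versatile_fraction_recovered`, `versatile_fraction_truth`,
#'   `versatile_fraction_bias`, and `versatile_fraction_truth_all` (over all
#'   simulated species, including ones the pipeline never saw).
#' @export
recovery_report <- function(truth, profiles) {
  m <- profile_matrix(profiles)
  sub <- truth[truth$species %in% rownames(m), ]
  if (nrow(sub) == 0) abort_stage("no overlap between truth and profiles")
  rec_sets <- lapply(sub$species, function(sp) {
    n_pathways()[m[sp, ] == 1L]
  })
  exact <- mapply(function(a, b) setequal(a, b), rec_sets, sub$pathways)
  rec_deg <- vapply(rec_sets, length, integer(1))
  vf_rec <- 100 * mean(rec_deg >= 2)
  vf_tru <- 100 * mean(sub$versatile)
  list(
    n_compared = nrow(sub),
    exact_match_rate = mean(exact),
    degree_mae = mean(abs(rec_deg - sub$degree)),
    versatile_fraction_recovered = vf_rec,
    versatile_fraction_truth = vf_tru,
    versatile_fraction_bias = vf_rec - vf_tru,
    versatile_fraction_truth_all = 100 * mean(truth$versatile)
  )
}
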