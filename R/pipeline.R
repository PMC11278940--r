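# End-to-end orchestration and machine-readable exports.

#' Export an UpSet-compatible membership matrix
#'
#' Writes the binary species x pathway matrix (one row per taxon, one 0/1
#' column per pathway in canonical order, header row) consumable by UpSet
#' plotting tools, and optionally the ranked exact-combination counts
#' (subset keys `+`-joined in canonical order).
#'
#' @param profiles a `profile_set`.
#' @param path output TSV path for the matrix.
#' @param combos_path optional output TSV for [combination_counts()].
#' @return `path`, invisibly.
#' @export
export_upset <- function(profiles, path, combos_path = NULL) {
  m <- profile_matrix(profiles)
  tb <- dplyr::bind_cols(tibble::tibble(taxon = rownames(m)),
                         tibble::as_tibble(m))
  readr::write_tsv(tb, path, progress = FALSE)
  if (!is.null(combos_path)) {
    readr::write_tsv(combination_counts(profiles), combos_path,
                     progress = FALSE)
  }
  invisible(path)
}

write_profiles_tsv <- function(profiles, path) {
  lin <- apply(as.matrix(profiles[, .RANKS]), 1, format_lineage)
  tb <- dplyr::bind_cols(
    tibble::tibble(taxon = profiles$taxon, lineage = lin),
    tibble::as_tibble(profile_matrix(profiles)),
    tibble::tibble(degree = profiles$degree,
                   n_samples_detected = profiles$n_samples_detected))
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

summarise_ecosystem <- function(table, ontology, min_prevalence,
                                other_threshold, rules, outdir, quiet) {
  label <- ecosystem_label(table)
  filt <- apply_prevalence_filter(table, min_prevalence, quiet = quiet)
  sp <- build_profiles(filt, ontology, level = "species")
  ge <- build_profiles(filt, ontology, level = "genus")
  dist_sp <- degree_distribution(sp)
  dist_ge <- degree_distribution(ge)
  vf_sp <- versatile_fraction(dist_sp)
  vf_ge <- versatile_fraction(dist_ge)
  combos <- combination_counts(sp)
  taxcomp <- taxonomic_composition(sp, versatile_only = TRUE,
                                   other_threshold = other_threshold)
  assign <- assign_guilds(filt, sp, rules)
  guilds <- lapply(c("AOA", "AOB", "NOB", "NFIXER"), function(g) {
    guild_summary(assign, sp, g)
  })
  names(guilds) <- c("AOA", "AOB", "NOB", "NFIXER")

  if (!is.null(outdir)) {
    dir.create(file.path(outdir, label), recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, label, f)
    write_profiles_tsv(sp, p("profiles_species.tsv"))
    write_profiles_tsv(ge, p("profiles_genus.tsv"))
    export_upset(sp, p("upset_matrix.tsv"), p("combination_counts.tsv"))
    readr::write_tsv(
      tibble::tibble(degree = 1:8, n_species = unname(dist_sp$counts),
                     n_genera = unname(dist_ge$counts)),
      p("degree_distribution.tsv"), progress = FALSE)
    readr::write_tsv(
      dplyr::mutate(assign,
                    evidence_genes = vapply(.data$evidence_genes, paste,
                                            character(1), collapse = ",")),
      p("guild_assignments.tsv"), progress = FALSE)
    jsonlite::write_json(lapply(guilds, guild_summary_json),
                         p("guild_summary.json"), auto_unbox = TRUE, digits = NA)
    for (g in names(guilds)) {
      if (guilds[[g]]$n_total > 0) {
        m <- heatmap_matrix(assign, sp, g, other_threshold)
        readr::write_tsv(
          dplyr::bind_cols(
            tibble::tibble(taxon = rownames(m),
                           taxon_group = attr(m, "taxon_annotation")),
            tibble::as_tibble(m)),
          p(sprintf("heatmap_%s.tsv", g)), progress = FALSE)
      }
    }
  }

  list(
    ecosystem = label,
    n_species = dist_sp$total,
    n_genera = dist_ge$total,
    degree_distribution = as.list(dist_sp$counts),
    versatile_species = vf_sp,
    versatile_genera = vf_ge,
    top_combinations = utils::head(combos, 10),
    taxonomic_composition = taxcomp,
    guilds = guilds,
    profiles_species = sp,
    profiles_genus = ge,
    assignments = assign
  )
}

guild_summary_json <- function(gs) {
  gs$top_combinations <- utils::head(gs$top_combinations, 10)
  gs
}

#' Run the full versatility pipeline
#'
#' Ingest (if paths are given) -> prevalence filter -> species and genus
#' pathway profiles -> versatility, combination and composition statistics
#' -> guild classification; when two or more ecosystems are supplied, the
#' pairwise species-registry overlaps are added. All module artifacts plus a
#' `summary.json` are written under `outdir` (one subdirectory per
#' ecosystem) when `outdir` is non-NULL.
#'
#' @param inputs named list: each element an `annotation_table` or a path to
#'   an annotation TSV; names are the ecosystem labels.
#' @param ontology_path optional ontology override TSV.
#' @param min_prevalence minimum distinct-sample prevalence (default 2).
#' @param other_threshold "Other" grouping threshold for compositions.
#' @param rules guild rules (built from the active ontology by default).
#' @param outdir output directory, or NULL to skip writing.
#' @param quiet suppress per-stage attrition messages.
#' @return a `summary` list: per-ecosystem blocks plus `overlap` when >= 2
#'   inputs.
#' @export
run_pipeline <- function(inputs, ontology_path = NULL, min_prevalence = 2,
                         other_threshold = 2, rules = NULL, outdir = NULL,
                         quiet = TRUE) {
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    abort_stage("inputs must be a named list (names are ecosystem labels)")
  }
  ontology <- load_pathway_ontology(ontology_path)
  rules <- rules %||% guild_rules(ontology = ontology)
  tables <- lapply(names(inputs), function(lab) {
    x <- inputs[[lab]]
    if (inherits(x, "annotation_table")) {
      new_annotation_table(x, lab)
    } else {
      read_annotations(x, ecosystem_label = lab, quiet = quiet)
    }
  })
  names(tables) <- names(inputs)
  eco <- lapply(tables, summarise_ecosystem, ontology = ontology,
                min_prevalence = min_prevalence,
                other_threshold = other_threshold, rules = rules,
                outdir = outdir, quiet = quiet)
  out <- list(ecosystems = eco)
  labs <- names(tables)
  if (length(labs) >= 2) {
    pairs <- utils::combn(labs, 2, simplify = FALSE)
    out$overlap <- lapply(pairs, function(pr) {
      ov <- ecosystem_overlap(eco[[pr[1]]]$profiles_species,
                              eco[[pr[2]]]$profiles_species)
      c(list(a = pr[1], b = pr[2]), ov)
    })
  }
  if (!is.null(outdir)) {
    jsonlite::write_json(summary_json(out), file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

summary_json <- function(out) {
  eco <- lapply(out$ecosystems, function(e) {
    list(
      ecosystem = e$ecosystem,
      n_species = e$n_species,
      n_genera = e$n_genera,
      degree_distribution = e$degree_distribution,
      versatile_species = e$versatile_species,
      versatile_genera = e$versatile_genera,
      top_combinations = e$top_combinations,
      taxonomic_composition = e$taxonomic_composition,
      guilds = lapply(e$guilds, guild_summary_json)
    )
  })
  list(ecosystems = eco, overlap = out$overlap)
}
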