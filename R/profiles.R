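# Prevalence filtering, pathway profiles, versatility statistics.

#' Number of distinct samples each species is detected in
#'
#' A species counts as detected in a sample if the sample holds at least one
#' annotation record of that species, for any gene — including genes the
#' ontology does not map to a pathway.
#'
#' @param table an `annotation_table`.
#' @return tibble with columns `species`, `n_samples`.
#' @export
species_sample_prevalence <- function(table) {
  table |>
    dplyr::distinct(.data$species, .data$sample_id) |>
    dplyr::count(.data$species, name = "n_samples") |>
    dplyr::arrange(.data$species)
}

#' Retain species detected in at least `min_prevalence` samples
#'
#' The occupancy rule for calling a species a resident of the ecosystem:
#' only species detected in more than one sample are analyzed further
#' (default `min_prevalence = 2`), which guards against spurious single-sample
#' annotations.
#'
#' @param table an `annotation_table`.
#' @param min_prevalence minimum number of distinct samples (>= 1).
#' @param quiet suppress the attrition message.
#' @return filtered `annotation_table` (same ecosystem label).
#' @export
apply_prevalence_filter <- function(table, min_prevalence = 2, quiet = TRUE) {
  if (!is.numeric(min_prevalence) || min_prevalence < 1) {
    abort_stage("min_prevalence must be >= 1 (got %s)",
                format(min_prevalence))
  }
  prev <- species_sample_prevalence(table)
  keep <- prev$species[prev$n_samples >= min_prevalence]
  dropped <- nrow(prev) - length(keep)
  if (!quiet) {
    message(sprintf("[%s] prevalence filter (>= %d samples): %d of %d species removed",
                    ecosystem_label(table), min_prevalence, dropped, nrow(prev)))
  }
  out <- table[table$species %in% keep, ]
  if (nrow(out) == 0) abort_stage("prevalence filter removed every species")
  new_annotation_table(out, ecosystem_label(table))
}

#' Build species- or genus-level pathway profiles
#'
#' At species level, pathway p is encoded by a species iff the species has at
#' least one record — in any sample, evidence pooled across samples — whose
#' gene maps to p in the ontology. Species carrying only unmapped genes are
#' excluded (each unknown gene triggers one warning). At genus level a genus'
#' vector is the union (logical OR) of its member species' vectors, so a
#' genus can be versatile even when none of its species is.
#'
#' @param table an `annotation_table`, already prevalence-filtered.
#' @param ontology a `pathway_ontology`.
#' @param level `"species"` or `"genus"`.
#' @param warn_unknown warn once per gene absent from the ontology.
#' @return a `profile_set`: tibble with columns `taxon`, the lineage ranks,
#'   one logical column per pathway (canonical order), `degree`,
#'   `n_samples_detected`; attributes `level` and `ecosystem`.
#' @export
build_profiles <- function(table, ontology = load_pathway_ontology(),
                           level = c("species", "genus"),
                           warn_unknown = FALSE) {
  level <- match.arg(level)
  codes <- n_pathways()
  known <- table$gene_key %in% ontology$key
  if (warn_unknown && any(!known)) {
    for (g in unique(table$gene[!known])) {
      warn_stage("gene '%s' not in ontology; its records are ignored by profiling", g)
    }
  }
  prev <- species_sample_prevalence(table)

  mapped <- table[known, ] |>
    dplyr::inner_join(
      tibble::tibble(gene_key = ontology$key, pathway = ontology$pathway),
      by = "gene_key", relationship = "many-to-many")
  if (nrow(mapped) == 0) abort_stage("no record maps to any pathway")

  prof <- mapped |>
    dplyr::distinct(.data$species, .data$pathway) |>
    dplyr::mutate(value = TRUE) |>
    tidyr::pivot_wider(names_from = "pathway", values_from = "value",
                       values_fill = FALSE)
  for (p in codes) if (!p %in% names(prof)) prof[[p]] <- FALSE

  lin <- table |>
    dplyr::distinct(dplyr::across(dplyr::all_of(.RANKS))) |>
    dplyr::distinct(.data$species, .keep_all = TRUE)
  prof <- prof |>
    dplyr::left_join(lin, by = "species") |>
    dplyr::left_join(prev, by = "species")

  if (level == "species") {
    out <- tibble::tibble(taxon = prof$species) |>
      dplyr::bind_cols(prof[, .RANKS], prof[, codes]) |>
      dplyr::mutate(n_samples_detected = prof$n_samples)
  } else {
    flagged <- sum(prof$genus == "")
    if (flagged > 0) {
      warn_stage("%d species without genus rank excluded from genus-level profiles",
                 flagged)
      prof <- prof[prof$genus != "", ]
    }
    g <- prof |>
      dplyr::group_by(.data$domain, .data$phylum, .data$class, .data$order,
                      .data$family, .data$genus) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(codes), any),
                       n_samples_detected = max(.data$n_samples),
                       .groups = "drop")
    out <- tibble::tibble(taxon = g$genus,
                          domain = g$domain, phylum = g$phylum,
                          class = g$class, order = g$order,
                          family = g$family, genus = g$genus,
                          species = "") |>
      dplyr::bind_cols(g[, codes]) |>
      dplyr::mutate(n_samples_detected = g$n_samples_detected)
  }
  out$degree <- as.integer(rowSums(as.matrix(out[, codes])))
  out <- out[out$degree >= 1, ]
  out <- dplyr::arrange(out, .data$taxon)
  structure(out, class = c("profile_set", class(out)),
            level = level, ecosystem = ecosystem_label(table))
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %s level, '%s': %d taxa, %d versatile\n",
              attr(x, "level"), attr(x, "ecosystem"),
              nrow(x), sum(x$degree >= 2)))
  NextMethod()
}

profile_matrix <- function(profiles) {
  m <- as.matrix(profiles[, n_pathways()]) * 1L
  rownames(m) <- profiles$taxon
  m
}

#' Distribution of pathway degree over taxa
#'
#' Degree = number of distinct pathways a taxon encodes (1-8).
#'
#' @param profiles a `profile_set`.
#' @return list with `counts` (named integer vector over degrees 1..8),
#'   `total`, and `versatile_total` (degree >= 2).
#' @export
degree_distribution <- function(profiles) {
  counts <- vapply(1:8, function(k) sum(profiles$degree == k), integer(1))
  names(counts) <- as.character(1:8)
  list(counts = counts,
       total = nrow(profiles),
       versatile_total = sum(counts[2:8]))
}

#' Versatile fraction of a degree distribution
#'
#' A taxon is metabolically versatile when it encodes two or more pathways.
#'
#' @param dist result of [degree_distribution()].
#' @return list: `count`, `percent_raw` (unrounded), `percent_display`
#'   (nearest integer, half away from zero).
#' @export
versatile_fraction <- function(dist) {
  if (dist$total == 0) abort_stage("empty profile set: versatile fraction undefined")
  count <- sum(dist$counts[as.character(2:8)])
  raw <- 100 * count / dist$total
  list(count = as.integer(count), percent_raw = raw,
       percent_display = round_half_up(raw))
}

combo_key <- function(mat_row) {
  paste(n_pathways()[as.logical(mat_row)], collapse = "+")
}

#' Exact pathway-combination counts (UpSet distinct mode)
#'
#' Each taxon is counted exactly once, under its exact pathway set — the
#' "distinct" intersection semantics of UpSet diagrams, not inclusive
#' superset counting. Combinations are keyed by `+`-joined pathway codes in
#' canonical order. Ties in the ranking are broken by smaller subset size,
#' then canonical key order.
#'
#' @param profiles a `profile_set`.
#' @return tibble with columns `combo` (key), `size` (subset size), `n`,
#'   sorted by decreasing `n`.
#' @export
combination_counts <- function(profiles) {
  m <- profile_matrix(profiles)
  keys <- unname(apply(m, 1, combo_key))
  tb <- tibble::tibble(combo = keys) |>
    dplyr::count(.data$combo, name = "n") |>
    dplyr::mutate(size = lengths(strsplit(.data$combo, "+", fixed = TRUE)),
                  rank_key = combo_rank_key(.data$combo)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$size, .data$rank_key) |>
    dplyr::select("combo", "size", "n")
  tb
}

combo_rank_key <- function(combos) {
  # lexicographic position of the subset in canonical pathway order
  vapply(strsplit(combos, "+", fixed = TRUE), function(ps) {
    paste(sprintf("%02d", sort(match(ps, n_pathways()))), collapse = "")
  }, character(1))
}

#' Taxonomic composition of (versatile) taxa
#'
#' Tallies taxa by display taxon (class for Proteobacteria, phylum
#' otherwise); labels carried by fewer than `other_threshold` taxa are merged
#' into `"Other"`. Percentages are over the selected subset and use the
#' package's display rounding.
#'
#' @param profiles a `profile_set`.
#' @param versatile_only restrict to taxa with degree >= 2.
#' @param other_threshold minimum taxa per label before merging into "Other".
#' @return tibble with `display_taxon`, `n`, `percent_raw`,
#'   `percent_display`, sorted by decreasing `n`.
#' @export
taxonomic_composition <- function(profiles, versatile_only = TRUE,
                                  other_threshold = 2) {
  sel <- if (versatile_only) profiles[profiles$degree >= 2, ] else profiles
  if (nrow(sel) == 0) {
    return(tibble::tibble(display_taxon = character(), n = integer(),
                          percent_raw = numeric(), percent_display = integer()))
  }
  lab <- display_taxon(sel$phylum, sel$class)
  tb <- tibble::tibble(display_taxon = lab) |>
    dplyr::count(.data$display_taxon, name = "n")
  rare <- tb$n < other_threshold & tb$display_taxon != "Other"
  if (any(rare)) {
    tb$display_taxon[rare] <- "Other"
    tb <- tb |>
      dplyr::group_by(.data$display_taxon) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
  }
  tb |>
    dplyr::mutate(percent_raw = 100 * .data$n / nrow(sel),
                  percent_display = round_half_up(.data$percent_raw)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$display_taxon)
}
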