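# Nitrifier (AOA/AOB/NOB) and nitrogen-fixer guild classification.

#' Classify nitrifier subgroups and nitrogen fixers
#'
#' A species is a nitrifier iff it carries at least one ammonia-oxidation or
#' nitrite-oxidation gene from the rules. Subgroup precedence (AOA > AOB >
#' NOB) makes the three labels a partition of the nitrifiers:
#' \itemize{
#'   \item archaeal lineage with any ammonia-oxidation gene: AOA;
#'   \item non-archaeal lineage with any ammonia-oxidation gene (amo, pmo or
#'     hao): AOB;
#'   \item otherwise, any nitrite-oxidoreductase carrier: NOB.
#' }
#' The nitrogen-fixer call (`nifHDK` evidence) is an independent flag that
#' can co-occur with a nitrifier label. Species carrying both ammonia- and
#' nitrite-oxidation genes (comammox-like) keep their precedence label but
#' are flagged `dual_evidence`; species whose only ammonia-oxidation
#' evidence is a pmo gene are flagged `pmo_only` as putative methanotroph
#' cross-hits.
#'
#' @param table prevalence-filtered `annotation_table`.
#' @param profiles `profile_set` built from the same table (species level).
#' @param rules a [guild_rules()] object.
#' @return tibble: `species`, `guild` (AOA/AOB/NOB/NONE), `nfixer` (logical),
#'   `evidence_genes` (list column), `dual_evidence`, `pmo_only`.
#' @export
assign_guilds <- function(table, profiles, rules = guild_rules()) {
  stopifnot(attr(profiles, "level") == "species")
  gs <- table |>
    dplyr::distinct(.data$species, .data$domain, .data$gene_key) |>
    dplyr::group_by(.data$species, .data$domain) |>
    dplyr::summarise(genes = list(sort(unique(.data$gene_key))),
                     .groups = "drop")
  in_profiles <- gs$species %in% profiles$taxon
  if (any(!in_profiles)) {
    warn_stage("%d species in table absent from profiles; skipped",
               sum(!in_profiles))
    gs <- gs[in_profiles, ]
  }
  amo <- rules$ammonia_oxidation_genes
  nxr <- rules$nitrite_oxidation_genes
  nif <- rules$fixation_genes
  pmo_genes <- amo[startsWith(amo, "pmo")]

  has_amo <- vapply(gs$genes, function(g) any(g %in% amo), logical(1))
  has_nxr <- vapply(gs$genes, function(g) any(g %in% nxr), logical(1))
  has_nif <- vapply(gs$genes, function(g) any(g %in% nif), logical(1))
  amo_pmo_only <- vapply(gs$genes, function(g) {
    hits <- g[g %in% amo]
    length(hits) > 0 && all(hits %in% pmo_genes)
  }, logical(1))
  archaeal <- gs$domain %in% rules$archaeal_domain_labels

  guild <- rep("NONE", nrow(gs))
  guild[has_nxr] <- "NOB"
  guild[has_amo & !archaeal] <- "AOB"
  guild[has_amo & archaeal] <- "AOA"

  ev <- Map(function(g) g[g %in% c(amo, nxr, nif)], gs$genes)
  tibble::tibble(
    species = gs$species,
    guild = guild,
    nfixer = has_nif,
    evidence_genes = unname(ev),
    dual_evidence = has_amo & has_nxr,
    pmo_only = amo_pmo_only
  )
}

guild_members <- function(assignments, guild) {
  if (guild == "NFIXER") {
    assignments$species[assignments$nfixer]
  } else {
    assignments$species[assignments$guild == guild]
  }
}

defining_pathway <- function(guild) {
  if (guild == "NFIXER") "NITROGEN_FIXATION" else "NITRIFICATION"
}

#' Pure-vs-versatile summary for a guild
#'
#' A guild member is "pure" when its profile degree is 1 and that single
#' pathway is the guild's defining pathway (nitrification for AOA/AOB/NOB,
#' nitrogen fixation for fixers); everyone else is versatile.
#' `top_combinations` ranks the exact sets of accompanying (non-defining)
#' pathways among versatile members, in distinct mode.
#'
#' @param assignments output of [assign_guilds()].
#' @param profiles species-level `profile_set`.
#' @param guild one of `"AOA"`, `"AOB"`, `"NOB"`, `"NFIXER"`.
#' @return list: `guild`, `n_total`, `n_pure`, `n_versatile`,
#'   `percent_pure`, `percent_versatile` (display-rounded),
#'   `top_combinations` tibble (`accompanying`, `n`, `percent_raw`,
#'   `percent_display`).
#' @export
guild_summary <- function(assignments, profiles, guild) {
  guild <- match.arg(guild, c("AOA", "AOB", "NOB", "NFIXER"))
  members <- guild_members(assignments, guild)
  sub <- profiles[profiles$taxon %in% members, ]
  def <- defining_pathway(guild)
  n_total <- nrow(sub)
  if (n_total == 0) {
    return(list(guild = guild, n_total = 0L, n_pure = 0L, n_versatile = 0L,
                percent_pure = 0L, percent_versatile = 0L,
                top_combinations = tibble::tibble(
                  accompanying = character(), n = integer(),
                  percent_raw = numeric(), percent_display = integer())))
  }
  pure <- sub$degree == 1 & sub[[def]]
  versatile <- !pure
  m <- profile_matrix(sub[versatile, , drop = FALSE])
  other <- setdiff(n_pathways(), def)
  keys <- unname(apply(m[, other, drop = FALSE], 1, function(r) {
    paste(other[as.logical(r)], collapse = "+")
  }))
  keys <- keys[keys != ""]  # members versatile without the defining pathway? degree>=2 always has some accompanying unless !def; keep non-empty sets
  top <- tibble::tibble(accompanying = keys) |>
    dplyr::count(.data$accompanying, name = "n") |>
    dplyr::mutate(
      size = lengths(strsplit(.data$accompanying, "+", fixed = TRUE)),
      rank_key = combo_rank_key(.data$accompanying),
      percent_raw = 100 * .data$n / n_total,
      percent_display = round_half_up(.data$percent_raw)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$size, .data$rank_key) |>
    dplyr::select("accompanying", "n", "percent_raw", "percent_display")
  list(
    guild = guild,
    n_total = as.integer(n_total),
    n_pure = as.integer(sum(pure)),
    n_versatile = as.integer(sum(versatile)),
    percent_pure = round_half_up(100 * sum(pure) / n_total),
    percent_versatile = round_half_up(100 * sum(versatile) / n_total),
    top_combinations = top
  )
}

#' Guild pathway-presence matrix for heatmap export
#'
#' Rows are guild member species (sorted by display taxon, then name),
#' columns the 8 pathways in canonical order, entries 0/1. The returned
#' object carries a `taxon_annotation` attribute: the display taxon per row,
#' with labels held by fewer than `other_threshold` species merged into
#' `"Other"`.
#'
#' @param assignments output of [assign_guilds()].
#' @param profiles species-level `profile_set`.
#' @param guild guild code.
#' @param other_threshold minimum species per taxon label.
#' @return integer matrix (species x 8) with attribute `taxon_annotation`.
#' @export
heatmap_matrix <- function(assignments, profiles, guild, other_threshold = 2) {
  members <- guild_members(assignments, guild)
  sub <- profiles[profiles$taxon %in% members, ]
  lab <- display_taxon(sub$phylum, sub$class)
  tallies <- table(lab)
  lab[tallies[lab] < other_threshold] <- "Other"
  ord <- order(lab, sub$taxon)
  sub <- sub[ord, ]
  m <- profile_matrix(sub)
  attr(m, "taxon_annotation") <- lab[ord]
  m
}
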