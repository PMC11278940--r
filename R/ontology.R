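# Pathway enumeration, gene-family -> pathway ontology, guild rules.

# Canonical ordinal order of the eight nitrogen-transformation pathways.
# This order is used everywhere presence vectors, matrices and combination
# keys are serialized; do not reorder.
.PATHWAY_CODES <- c(
  "AMMONIA_ASSIMILATION",
  "ASSIM_NITRATE_REDUCTION",
  "DISSIM_NITRATE_TO_NITRITE",
  "DISSIM_NITRITE_TO_AMMONIA",
  "DENITRIFICATION",
  "NITRIFICATION",
  "NITROGEN_FIXATION",
  "ANAMMOX"
)

.PATHWAY_LABELS <- c(
  AMMONIA_ASSIMILATION      = "ammonia assimilation",
  ASSIM_NITRATE_REDUCTION   = "assimilatory nitrate reduction",
  DISSIM_NITRATE_TO_NITRITE = "dissimilatory nitrate to nitrite",
  DISSIM_NITRITE_TO_AMMONIA = "dissimilatory nitrite to ammonia",
  DENITRIFICATION           = "denitrification",
  NITRIFICATION             = "nitrification",
  NITROGEN_FIXATION         = "nitrogen fixation",
  ANAMMOX                   = "anammox"
)

#' The eight nitrogen-transformation pathways
#'
#' Returns the canonical eight-pathway enumeration in its fixed ordinal
#' order: ammonia assimilation, assimilatory nitrate reduction,
#' dissimilatory nitrate to nitrite, dissimilatory nitrite to ammonia,
#' denitrification, nitrification, nitrogen fixation, anammox. All
#' presence/absence vectors and serialized matrices in the package use this
#' order.
#'
#' @param labels if `TRUE`, return a named character vector of human-readable
#'   labels instead of the bare codes.
#' @return character vector of length 8.
#' @examples
#' n_pathways()
#' n_pathways(labels = TRUE)[["NITRIFICATION"]]
#' @export
n_pathways <- function(labels = FALSE) {
  if (labels) .PATHWAY_LABELS else .PATHWAY_CODES
}

#' Load a gene-family to pathway ontology
#'
#' Reads the mapping from nitrogen-cycle gene families (e.g. `amoA`, `nifH`,
#' `nosZ`) to the eight pathways. Without a path the curated builtin table is
#' returned; with a path, rows from the file are merged over the builtin map
#' (a gene present in the file replaces that gene's builtin pathway set
#' entirely, so users can load the authoritative database category table).
#'
#' The file format is a two-column TSV with header
#' `gene_family<TAB>pathway`, one row per (gene, pathway) pair; `#` comment
#' lines are ignored. A gene may map to more than one pathway. Gene keys are
#' case-insensitive.
#'
#' @param path optional path to a TSV override/extension table.
#' @return an object of class `pathway_ontology`: a tibble with columns
#'   `gene` (display name), `key` (lower-cased), `pathway`, plus a `source`
#'   attribute.
#' @examples
#' ont <- load_pathway_ontology()
#' pathways_of(ont, "nifH")
#' @export
load_pathway_ontology <- function(path = NULL) {
  builtin <- system.file("extdata", "pathway_map.tsv", package = "nversa")
  tbl <- read_ontology_tsv(builtin)
  src <- "builtin"
  if (!is.null(path)) {
    user <- read_ontology_tsv(path)
    # user-listed genes override the builtin pathway set wholesale
    tbl <- dplyr::bind_rows(tbl[!(tbl$key %in% user$key), ], user)
    src <- path
  }
  new_pathway_ontology(tbl, source = src)
}

read_ontology_tsv <- function(path) {
  if (!file.exists(path)) {
    abort_stage("ontology file not found: %s", path)
  }
  raw <- readr::read_tsv(path, comment = "#", col_types = "cc",
                         progress = FALSE)
  if (!all(c("gene_family", "pathway") %in% names(raw))) {
    abort_stage("ontology TSV must have columns 'gene_family' and 'pathway': %s",
                path)
  }
  if (nrow(raw) == 0) {
    abort_stage("ontology file is empty: %s", path)
  }
  bad <- !(raw$pathway %in% .PATHWAY_CODES)
  if (any(bad)) {
    i <- which(bad)[1]
    abort_stage("unknown pathway code '%s' for gene '%s' (row %d of %s)",
                raw$pathway[i], raw$gene_family[i], i, path)
  }
  if (any(raw$gene_family == "" | is.na(raw$gene_family))) {
    abort_stage("empty gene_family in ontology file %s", path)
  }
  tbl <- tibble::tibble(
    gene = raw$gene_family,
    key = tolower(raw$gene_family),
    pathway = raw$pathway
  )
  dup <- duplicated(tbl[, c("key", "pathway")])
  if (any(dup)) {
    warn_stage("%d duplicate (gene, pathway) rows in %s; deduplicated",
               sum(dup), path)
    tbl <- tbl[!dup, ]
  }
  tbl
}

new_pathway_ontology <- function(tbl, source) {
  stopifnot(all(tbl$pathway %in% .PATHWAY_CODES))
  tbl <- dplyr::arrange(tbl, .data$key,
                        match(.data$pathway, .PATHWAY_CODES))
  structure(tbl, class = c("pathway_ontology", class(tbl)), source = source)
}

#' @export
print.pathway_ontology <- function(x, ...) {
  cat(sprintf("<pathway_ontology> %d genes, %d (gene, pathway) pairs [%s]\n",
              length(unique(x$key)), nrow(x), attr(x, "source")))
  invisible(x)
}

#' Pathways mapped to a gene family
#'
#' Case-insensitive lookup. Genes absent from the ontology return an empty
#' character vector; the caller decides whether that is worth a warning.
#'
#' @param ontology a `pathway_ontology`.
#' @param gene gene-family symbol (scalar character).
#' @return character vector of pathway codes in canonical order (possibly
#'   empty).
#' @export
pathways_of <- function(ontology, gene) {
  stopifnot(inherits(ontology, "pathway_ontology"), length(gene) == 1)
  hits <- ontology$pathway[ontology$key == tolower(gene)]
  .PATHWAY_CODES[.PATHWAY_CODES %in% hits]
}

#' Write an ontology back to TSV
#'
#' Inverse of [load_pathway_ontology()]: the written file reloads to an
#' identical mapping.
#'
#' @param ontology a `pathway_ontology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_ontology <- function(ontology, path) {
  readr::write_tsv(
    tibble::tibble(gene_family = ontology$gene, pathway = ontology$pathway),
    path, progress = FALSE
  )
  invisible(path)
}

#' Guild classification rules
#'
#' Gene sets that define the nitrifier and nitrogen-fixer guilds: ammonia
#' oxidation evidence (ammonia monooxygenase `amoCAB`, methane monooxygenase
#' `pmoCAB`, hydroxylamine oxidoreductase `hao`), nitrite oxidation evidence
#' (nitrite oxidoreductase `nxrAB`), and nitrogenase genes (`nifHDK`). The
#' three sets must be pairwise disjoint and every member must exist in the
#' active ontology.
#'
#' @param ammonia_oxidation_genes,nitrite_oxidation_genes,fixation_genes
#'   character vectors of gene symbols.
#' @param archaeal_domain_labels lineage domain strings treated as archaeal.
#' @param ontology ontology used to validate membership.
#' @return an object of class `guild_rules`.
#' @export
guild_rules <- function(ammonia_oxidation_genes = c("amoA", "amoB", "amoC",
                                                    "pmoA", "pmoB", "pmoC",
                                                    "hao"),
                        nitrite_oxidation_genes = c("nxrA", "nxrB"),
                        fixation_genes = c("nifH", "nifD", "nifK"),
                        archaeal_domain_labels = c("Archaea"),
                        ontology = load_pathway_ontology()) {
  amo <- tolower(ammonia_oxidation_genes)
  nxr <- tolower(nitrite_oxidation_genes)
  nif <- tolower(fixation_genes)
  if (length(intersect(amo, nxr)) || length(intersect(amo, nif)) ||
      length(intersect(nxr, nif))) {
    abort_stage("guild gene sets must be pairwise disjoint")
  }
  known <- unique(ontology$key)
  missing <- setdiff(c(amo, nxr, nif), known)
  if (length(missing)) {
    abort_stage("guild rule genes absent from ontology: %s",
                paste(missing, collapse = ", "))
  }
  structure(
    list(ammonia_oxidation_genes = amo,
         nitrite_oxidation_genes = nxr,
         fixation_genes = nif,
         archaeal_domain_labels = archaeal_domain_labels),
    class = "guild_rules"
  )
}
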