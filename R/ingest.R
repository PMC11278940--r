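# Reading per-sample gene-annotation tables and taxonomic lineages.

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
.RANK_PREFIXES <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Parse a semicolon-delimited taxonomic lineage
#'
#' Accepts either bare rank strings
#' (`"Bacteria;Proteobacteria;...;Bradyrhizobium japonicum"`) or the
#' prefixed dialect (`"d__Bacteria;p__...;s__..."`). Missing trailing ranks
#' are padded with empty strings; whitespace is trimmed; prefixes are
#' stripped.
#'
#' @param raw lineage string (scalar).
#' @param prefix_style `"auto"` (detect by presence of `d__`), `"bare"` or
#'   `"prefixed"`.
#' @return named character vector of the 7 ranks
#'   (domain, phylum, class, order, family, genus, species).
#' @examples
#' parse_lineage("Bacteria;Proteobacteria;Alphaproteobacteria")["domain"]
#' @export
parse_lineage <- function(raw, prefix_style = c("auto", "bare", "prefixed")) {
  prefix_style <- match.arg(prefix_style)
  parts <- trimws(strsplit(raw, ";", fixed = TRUE)[[1]])
  if (length(parts) > 7) {
    abort_stage("lineage has %d fields (max 7): '%s'", length(parts), raw)
  }
  if (prefix_style == "auto") {
    prefix_style <- if (any(startsWith(parts, "d__"))) "prefixed" else "bare"
  }
  if (prefix_style == "prefixed") {
    for (p in .RANK_PREFIXES) parts <- sub(paste0("^", p), "", parts)
  }
  out <- c(parts, rep("", 7 - length(parts)))
  names(out) <- .RANKS
  out
}

format_lineage <- function(ranks) {
  # drop trailing empties so short lineages round-trip verbatim
  last <- max(c(0, which(ranks != "")))
  paste(ranks[seq_len(last)], collapse = ";")
}

#' Display taxon for plotting and composition tables
#'
#' Returns the class name for Proteobacteria (the convention in this field:
#' Alphaproteobacteria, Betaproteobacteria, ... are reported as top-level
#' taxa) and the phylum otherwise; empty phylum maps to `"Unclassified"`.
#' Grouping of rare labels into `"Other"` happens downstream
#' (see [taxonomic_composition()]).
#'
#' @param phylum,class character vectors (recycled together).
#' @return character vector of display labels.
#' @export
display_taxon <- function(phylum, class = "") {
  n <- max(length(phylum), length(class))
  phylum <- rep_len(phylum, n)
  class <- rep_len(class, n)
  out <- ifelse(phylum == "" | is.na(phylum), "Unclassified", phylum)
  proteo <- !is.na(phylum) & phylum == "Proteobacteria" &
    !is.na(class) & class != ""
  out[proteo] <- class[proteo]
  out
}

new_annotation_table <- function(records, ecosystem_label) {
  records <- tibble::as_tibble(records)
  structure(records,
            class = c("annotation_table", class(records)),
            ecosystem = ecosystem_label)
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> '%s': %d records, %d samples, %d species\n",
              attr(x, "ecosystem"), nrow(x),
              length(unique(x$sample_id)), length(unique(x$species))))
  NextMethod()
}

#' Ecosystem label of an annotation table
#' @param table an `annotation_table`.
#' @return character scalar.
#' @export
ecosystem_label <- function(table) attr(table, "ecosystem")

#' Read a per-sample gene-annotation TSV
#'
#' Expects header columns `sample_id`, `gene_family`, `lineage` and an
#' optional `count` (missing or empty counts default to 1). The lineage is a
#' semicolon-delimited rank string in either bare or `d__`-prefixed dialect
#' (auto-detected per row). Normalization: rows whose species rank is empty
#' are dropped (with a tally), zero-count rows are dropped, and duplicate
#' (sample, gene, species) triples are merged by summing counts.
#'
#' @param path TSV file (gzip accepted via readr).
#' @param ecosystem_label free-text label, e.g. `"soil"` or `"marine"`.
#' @param quiet suppress the attrition message.
#' @return an `annotation_table`: a tibble with columns `sample_id`, `gene`,
#'   `gene_key`, the 7 lineage ranks, and `count`.
#' @export
read_annotations <- function(path, ecosystem_label = "ecosystem",
                             quiet = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("sample_id", "gene_family", "lineage")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort_stage("annotation TSV %s lacks mandatory column(s): %s",
                path, paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0) abort_stage("annotation TSV is empty: %s", path)
  if (!"count" %in% names(raw)) raw$count <- "1"
  raw$count[is.na(raw$count) | raw$count == ""] <- "1"
  count <- suppressWarnings(as.numeric(raw$count))
  bad <- which(is.na(count) | count < 0 | count != floor(count))
  if (length(bad)) {
    abort_stage("unparseable count '%s' at data line %d of %s",
                raw$count[bad[1]], bad[1], path)
  }
  ranks <- t(vapply(raw$lineage, parse_lineage, character(7)))
  rownames(ranks) <- NULL
  rec <- tibble::as_tibble(as.data.frame(ranks, stringsAsFactors = FALSE))
  rec <- dplyr::bind_cols(
    tibble::tibble(sample_id = raw$sample_id,
                   gene = raw$gene_family,
                   gene_key = tolower(raw$gene_family)),
    rec,
    tibble::tibble(count = as.integer(count))
  )
  normalize_annotations(rec, ecosystem_label, quiet = quiet,
                        n_raw = nrow(raw))
}

#' Build an annotation table from an in-memory record data frame
#'
#' Programmatic entry point used by the synthetic generator and tests; applies
#' the same normalization as [read_annotations()].
#'
#' @param records data frame with columns `sample_id`, `gene`, the 7 rank
#'   columns (missing ranks are filled with `""`), and optional `count`.
#' @param ecosystem_label free-text label.
#' @param quiet suppress the attrition message.
#' @return an `annotation_table`.
#' @export
annotation_table <- function(records, ecosystem_label = "ecosystem",
                             quiet = TRUE) {
  records <- tibble::as_tibble(records)
  for (r in .RANKS) if (!r %in% names(records)) records[[r]] <- ""
  if (!"count" %in% names(records)) records$count <- 1L
  if (!"gene_key" %in% names(records)) records$gene_key <- tolower(records$gene)
  normalize_annotations(records, ecosystem_label, quiet = quiet,
                        n_raw = nrow(records))
}

normalize_annotations <- function(rec, ecosystem_label, quiet, n_raw) {
  if (any(rec$sample_id == "" | is.na(rec$sample_id))) {
    abort_stage("empty sample_id in annotation input")
  }
  rec <- rec[rec$count > 0, ]
  n_no_species <- sum(rec$species == "" | is.na(rec$species))
  rec <- rec[rec$species != "" & !is.na(rec$species), ]
  if (nrow(rec) == 0) abort_stage("no usable annotation records after filtering")
  rec <- rec |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("sample_id", "gene_key", .RANKS)))) |>
    dplyr::summarise(gene = dplyr::first(.data$gene),
                     count = sum(.data$count), .groups = "drop") |>
    dplyr::relocate("sample_id", "gene", "gene_key")
  rec <- dplyr::arrange(rec, .data$sample_id, .data$species, .data$gene_key)
  if (!quiet) {
    message(sprintf(
      "[%s] ingested %d raw rows -> %d records (%d without species rank dropped)",
      ecosystem_label, n_raw, nrow(rec), n_no_species))
  }
  new_annotation_table(rec, ecosystem_label)
}

#' Write an annotation table back to TSV
#'
#' Emits the same 4-column schema consumed by [read_annotations()]
#' (`sample_id`, `gene_family`, `lineage`, `count`), so written tables
#' round-trip to identical records.
#'
#' @param table an `annotation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(table, path) {
  lineage <- apply(as.matrix(table[, .RANKS]), 1, format_lineage)
  readr::write_tsv(
    tibble::tibble(sample_id = table$sample_id,
                   gene_family = table$gene,
                   lineage = lineage,
                   count = table$count),
    path, progress = FALSE
  )
  invisible(path)
}
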