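# Cross-ecosystem species registry comparison.

#' Overlap of two species registries
#'
#' Compares the species name sets of two species-level profile sets (e.g.
#' soil vs. marine nitrogen-transforming species). Matching is exact string
#' equality on the species rank; no synonym resolution is attempted.
#'
#' @param profiles_a,profiles_b species-level `profile_set`s.
#' @return list: `n_a`, `n_b`, `n_shared`, `pct_a_only`, `pct_b_only`,
#'   `pct_shared_of_b` (display-rounded), their `_raw` counterparts, and
#'   `jaccard`.
#' @export
ecosystem_overlap <- function(profiles_a, profiles_b) {
  if (attr(profiles_a, "level") != "species" ||
      attr(profiles_b, "level") != "species") {
    abort_stage("ecosystem_overlap requires species-level profile sets")
  }
  a <- unique(profiles_a$taxon)
  b <- unique(profiles_b$taxon)
  shared <- length(intersect(a, b))
  n_a <- length(a); n_b <- length(b)
  raw_a_only <- 100 * (n_a - shared) / n_a
  raw_b_only <- 100 * (n_b - shared) / n_b
  raw_shared_b <- 100 * shared / n_b
  list(
    n_a = n_a, n_b = n_b, n_shared = shared,
    pct_a_only_raw = raw_a_only, pct_a_only = round_half_up(raw_a_only),
    pct_b_only_raw = raw_b_only, pct_b_only = round_half_up(raw_b_only),
    pct_shared_of_b_raw = raw_shared_b,
    pct_shared_of_b = round_half_up(raw_shared_b),
    jaccard = shared / length(union(a, b))
  )
}
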