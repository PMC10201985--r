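# Machine-readable fixtures of the published interface-interaction table and
# the combinations-by-residues centrality Z-score tables, shipped as TSV and
# loaded on demand. They are data, transcribed once; checksum tests guard
# against accidental edits.

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "cybrin")
  if (path == "") abort(paste0("fixture not found: ", file))
  path
}

#' Published interface interaction records
#'
#' The 28 tabulated plastid-nuclear interface residue pairs with their
#' per-lineage amino acids, minimal distance, interaction type before and
#' after mutation, and the derived change category. Cells printed as "no
#' mutation relative to the reference" are `NA`; lineage-dependent
#' post-mutation calls are kept verbatim as slash-separated variants (e.g.
#' `"hydrophobic/none"`).
#'
#' @return Tibble with one row per interaction record, including a
#'   `category` column (`loss`, `gain`, `type_change`, `unchanged`).
#' @export
table1_fixture <- function() {
  raw <- readr::read_tsv(fixture_path("table1_interactions.tsv"),
                         na = ".", show_col_types = FALSE, progress = FALSE)
  raw$category <- purrr::map2_chr(raw$type_before, raw$type_after,
                                  categorize_record)
  raw
}

#' Published centrality Z-score table
#'
#' The 16 plastid-nuclear combinations by 17 residues matrix of printed
#' Z-scores for the betweenness (BCA) or closeness (CCA) analysis. Residue
#' columns follow the `<number>.k` (plastid-encoded rps11) / `<number>.u`
#' (nuclear-encoded rps21) labelling; combination labels put the maternal
#' (plastid-donor) lineage first.
#'
#' @param measure `"BCA"` or `"CCA"`.
#' @return Wide tibble: `combination` plus 17 residue columns, with
#'   attribute `measure`.
#' @export
table3_fixture <- function(measure = c("BCA", "CCA")) {
  measure <- match.arg(measure)
  out <- readr::read_tsv(
    fixture_path(paste0("centrality_zscores_", tolower(measure), ".tsv")),
    show_col_types = FALSE, progress = FALSE
  )
  attr(out, "measure") <- measure
  out
}
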