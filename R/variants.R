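# Detection of amino-acid substitutions differentially fixed between
# lineages, and their mapping onto ungapped reference residue numbering.

#' Detect differentially fixed amino-acid differences
#'
#' Scans an aligned multi-lineage protein dataset column by column and
#' returns the columns that are monomorphic within every lineage but not
#' identical across lineages. Columns containing a gap in any sample
#' sequence are skipped, as are columns polymorphic within any lineage; the
#' reference sequence (lineage `"reference"`) takes no part in the fixation
#' test.
#'
#' @param alignment Tibble with columns `gene`, `seq_id`, `lineage`,
#'   `sequence` (all sequences of a gene equal length).
#' @return Tibble with one row per fixed difference: `gene`, `column`, plus
#'   one amino-acid column per lineage.
#' @export
detect_fixed_differences <- function(alignment) {
  alignment <- as_tibble(alignment)
  samples <- alignment[alignment$lineage != "reference", ]
  if (nrow(samples) == 0) abort("alignment has no sample sequences")
  purrr::map_dfr(unique(samples$gene), function(g) {
    sub <- samples[samples$gene == g, ]
    lens <- nchar(sub$sequence)
    if (length(unique(lens)) != 1) {
      abort(paste0("ragged alignment for gene ", g,
                   ": sequence lengths ", paste(unique(lens), collapse = ", ")))
    }
    lineages <- unique(sub$lineage)
    mat <- do.call(rbind, strsplit(sub$sequence, ""))
    keep <- purrr::map_lgl(seq_len(ncol(mat)), function(j) {
      col <- mat[, j]
      if (any(col %in% c("-", "."))) return(FALSE)
      per_lin <- tapply(col, sub$lineage, function(x) length(unique(x)))
      if (any(per_lin > 1)) return(FALSE)
      fixed <- tapply(col, sub$lineage, function(x) x[1])
      length(unique(fixed)) > 1
    })
    if (!any(keep)) {
      out <- tibble(gene = character(0), column = integer(0))
      for (li in lineages) out[[li]] <- character(0)
      return(out)
    }
    purrr::map_dfr(which(keep), function(j) {
      fixed <- tapply(mat[, j], sub$lineage, function(x) x[1])
      row <- tibble(gene = g, column = as.integer(j))
      for (li in lineages) row[[li]] <- unname(fixed[li])
      row
    })
  })
}

#' Map alignment columns to reference residue numbering
#'
#' Converts each substitution's alignment column to the 1-based ungapped
#' residue number of the reference sequence and records the reference amino
#' acid. Columns aligned to a reference gap are flagged `unmappable` (with
#' `NA` number), never silently dropped. An optional per-gene offset
#' reconciles sequence numbering with the deposited structure's author
#' numbering.
#'
#' @param subs Substitution tibble from [detect_fixed_differences()].
#' @param alignment Alignment tibble containing the reference rows
#'   (`lineage == "reference"`), or a named character vector of aligned
#'   reference sequences by gene.
#' @param offsets Optional named integer vector of per-gene numbering
#'   offsets (default 0).
#' @return `subs` with `ref_number`, `ref_aa` and `unmappable` columns.
#' @export
map_to_reference <- function(subs, alignment, offsets = NULL) {
  refs <- if (is.character(alignment)) {
    alignment
  } else {
    aln <- as_tibble(alignment)
    ref_rows <- aln[aln$lineage == "reference", ]
    if (nrow(ref_rows) == 0) abort("alignment has no reference sequence")
    setNames(ref_rows$sequence, ref_rows$gene)
  }
  subs <- as_tibble(subs)
  missing_ref <- setdiff(unique(subs$gene), names(refs))
  if (length(missing_ref) > 0) {
    abort(paste0("no reference sequence for gene(s): ",
                 paste(missing_ref, collapse = ", ")))
  }
  out <- purrr::map_dfr(unique(subs$gene), function(g) {
    sub <- subs[subs$gene == g, ]
    ref_chars <- strsplit(refs[[g]], "")[[1]]
    if (any(sub$column > length(ref_chars))) {
      abort(paste0("substitution column beyond reference length for ", g))
    }
    ref_no <- cumsum(!ref_chars %in% c("-", "."))
    off <- if (!is.null(offsets) && g %in% names(offsets)) offsets[[g]] else 0L
    gap <- ref_chars[sub$column] %in% c("-", ".")
    sub$ref_number <- ifelse(gap, NA_integer_,
                             as.integer(ref_no[sub$column]) + as.integer(off))
    sub$ref_aa <- ifelse(gap, NA_character_, ref_chars[sub$column])
    sub$unmappable <- gap
    sub
  })
  arrange(out, .data$gene, .data$column)
}

#' Per-lineage substitution sets relative to the reference
#'
#' For each lineage, keeps the positions where that lineage's fixed amino
#' acid differs from the reference amino acid; positions equal to the
#' reference are omitted (nothing to model there). Unmappable positions are
#' excluded.
#'
#' @param subs Mapped substitution tibble from [map_to_reference()].
#' @param lineages Lineage labels (must all appear as columns of `subs`).
#' @return Long tibble: `lineage`, `gene`, `ref_number`, `ref_aa`, `new_aa`.
#' @export
build_substitution_sets <- function(subs, lineages) {
  subs <- as_tibble(subs)
  missing_lin <- setdiff(lineages, names(subs))
  if (length(missing_lin) > 0) {
    abort(paste0("lineage(s) absent from substitution table: ",
                 paste(missing_lin, collapse = ", ")))
  }
  mapped <- subs[!subs$unmappable, ]
  purrr::map_dfr(lineages, function(li) {
    keep <- mapped[[li]] != mapped$ref_aa
    tibble(
      lineage = li,
      gene = mapped$gene[keep],
      ref_number = mapped$ref_number[keep],
      ref_aa = mapped$ref_aa[keep],
      new_aa = mapped[[li]][keep]
    )
  }) |>
    arrange(.data$lineage, .data$gene, .data$ref_number)
}
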