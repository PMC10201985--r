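# In-silico point mutagenesis: side chains are rebuilt from idealized
# templates superposed on the residue's own backbone, oriented by a coarse
# rotamer search that minimizes a heavy-atom clash count, with an optional
# deterministic chi-grid relaxation.

backbone_atoms <- c("N", "CA", "C", "O", "OXT")

residue_backbone <- function(res) {
  need <- c("N", "CA", "C")
  miss <- setdiff(need, res$atom)
  if (length(miss) > 0) {
    abort(paste0("residue lacks backbone atom(s): ", paste(miss, collapse = ", ")))
  }
  coord <- function(name) {
    row <- res[res$atom == name, ][1, ]
    c(row$x, row$y, row$z)
  }
  list(N = coord("N"), CA = coord("CA"), C = coord("C"))
}

clash_count <- function(side_mat, rest_mat, threshold = 2.5) {
  if (nrow(side_mat) == 0 || nrow(rest_mat) == 0) return(0L)
  d2 <- outer(rowSums(side_mat^2), rowSums(rest_mat^2), "+") -
    2 * tcrossprod(side_mat, rest_mat)
  sum(d2 < threshold^2)
}

#' Choose the least-clashing rotamer for a residue
#'
#' Evaluates every candidate chi combination by rebuilding the side chain on
#' the residue's backbone and counting heavy-atom contacts closer than
#' `threshold` against all atoms of every other residue (the residue's own
#' backbone is excluded). The candidate with the lowest clash count wins;
#' ties are broken by higher library prior, then by lowest chi-angle
#' lexicographic order, so the choice is fully deterministic.
#'
#' @param s A structure tibble.
#' @param chain,number,icode Identify the target residue (its backbone is
#'   used; any existing side chain is ignored).
#' @param aa3 Three-letter name of the residue type to place.
#' @param candidates Optional candidate tibble as from [rotamer_candidates()].
#' @param threshold Clash distance in Angstrom.
#' @return Numeric vector of chi angles (possibly length 0), with attributes
#'   `clash` and `prior`.
#' @export
choose_rotamer <- function(s, chain, number, aa3, icode = "",
                           candidates = NULL, threshold = 2.5) {
  aa3 <- toupper(aa3)
  res <- residue_atoms(s, chain, number, icode)
  bb <- residue_backbone(res)
  candidates <- candidates %||% rotamer_candidates(aa3)
  if (nrow(candidates) == 0) abort("empty rotamer candidate set")
  own <- s$chain_id == chain & s$resno == number & s$icode == icode
  rest <- as.matrix(s[!own, c("x", "y", "z")])
  chi_cols <- grep("^chi[0-9]$", names(candidates), value = TRUE)
  scores <- purrr::map_int(seq_len(nrow(candidates)), function(i) {
    chis <- as.numeric(candidates[i, chi_cols])
    side <- build_side_chain(aa3, bb, chis)
    clash_count(as.matrix(side[, c("x", "y", "z")]), rest, threshold)
  })
  lex_pos <- if (length(chi_cols) == 0) {
    seq_len(nrow(candidates))
  } else {
    lex_rank <- do.call(order, as.list(candidates[chi_cols]))
    match(seq_len(nrow(candidates)), lex_rank)
  }
  best <- order(scores, -candidates$prior, lex_pos)[1]
  chis <- as.numeric(candidates[best, chi_cols])
  names(chis) <- chi_cols
  attr(chis, "clash") <- scores[best]
  attr(chis, "prior") <- candidates$prior[best]
  chis
}

splice_side_chain <- function(s, chain, number, icode, aa3, side) {
  own <- s$chain_id == chain & s$resno == number & s$icode == icode
  keep_bb <- s[own & s$atom %in% backbone_atoms, ]
  keep_bb$resname <- aa3
  keep_bb$standard <- aa3 %in% aa_codes()$aa3
  meta <- keep_bb[1, ]
  new_rows <- tibble(
    chain_id = meta$chain_id, protein = meta$protein,
    compartment = meta$compartment, resno = meta$resno, icode = meta$icode,
    resname = aa3, atom = side$atom, element = side$element,
    x = side$x, y = side$y, z = side$z,
    occupancy = 1, altloc = "", standard = keep_bb$standard[1]
  )
  out <- bind_rows(s[!own, ], keep_bb, new_rows)
  arrange(out, .data$chain_id, .data$resno, .data$icode,
          match(.data$atom, c(backbone_atoms, out$atom)))
}

#' Substitute one residue
#'
#' Replaces a residue's side chain with the idealized side chain of another
#' amino acid. Backbone atoms (N, CA, C, O) are left untouched; the new side
#' chain is built on the existing backbone with chi angles from
#' [choose_rotamer()] and optionally relaxed on a chi grid. A glycine target
#' removes the side chain entirely.
#'
#' @param s A structure tibble.
#' @param chain,number,icode Identify the target residue.
#' @param new_aa One-letter code of the replacement amino acid.
#' @param relax If `TRUE`, run [relax_side_chain()] after placement.
#' @return The mutated structure tibble.
#' @export
substitute_residue <- function(s, chain, number, new_aa, icode = "", relax = FALSE) {
  targets <- tibble(chain_id = chain, resno = number, icode = icode, new_aa = new_aa)
  substitute_residues(s, targets, relax = relax)
}

#' Substitute several residues deterministically
#'
#' All target side chains are first stripped to the backbone, then rebuilt
#' one at a time in (chain, residue number) order. Stripping first makes the
#' operation idempotent: re-applying the same substitution set reproduces the
#' same intermediate environments and therefore the same rotamer choices.
#'
#' @param s A structure tibble.
#' @param targets Tibble with columns `chain_id`, `resno`, `new_aa` and
#'   optionally `icode`.
#' @param relax If `TRUE`, chi-grid relax each rebuilt side chain.
#' @return The mutated structure tibble.
#' @export
substitute_residues <- function(s, targets, relax = FALSE) {
  s <- as_structure(s)
  targets <- as_tibble(targets)
  if (!"icode" %in% names(targets)) targets$icode <- ""
  targets <- arrange(targets, .data$chain_id, .data$resno, .data$icode)
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    res <- residue_atoms(s, tg$chain_id, tg$resno, tg$icode)
    if (!res$standard[1]) {
      abort(paste0("cannot substitute non-standard residue ", res$resname[1],
                   " at ", tg$chain_id, ":", tg$resno))
    }
  }
  aa3_new <- aa1_to_aa3(targets$new_aa)
  # phase 1: strip all target side chains and rename
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    own <- s$chain_id == tg$chain_id & s$resno == tg$resno & s$icode == tg$icode
    s <- s[!(own & !(s$atom %in% backbone_atoms)), ]
    s$resname[s$chain_id == tg$chain_id & s$resno == tg$resno &
                s$icode == tg$icode] <- aa3_new[i]
  }
  # phase 2: rebuild in order
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    if (aa3_new[i] == "GLY") next
    chis <- choose_rotamer(s, tg$chain_id, tg$resno, aa3_new[i], tg$icode)
    bb <- residue_backbone(residue_atoms(s, tg$chain_id, tg$resno, tg$icode))
    side <- build_side_chain(aa3_new[i], bb, as.numeric(chis))
    s <- splice_side_chain(s, tg$chain_id, tg$resno, tg$icode, aa3_new[i], side)
    if (relax) s <- relax_side_chain(s, tg$chain_id, tg$resno, tg$icode)
  }
  as_structure(s)
}

#' Relax a rebuilt side chain on a chi-angle grid
#'
#' Deterministic cyclic coordinate descent over the residue's chi angles:
#' each chi in turn is scanned over a 15-degree grid (keeping the others
#' fixed) and set to the value minimizing the heavy-atom clash count; sweeps
#' repeat until no chi changes. Ties prefer the incumbent value, then the
#' smallest angle, so the clash score never increases and the result is
#' reproducible. The backbone is untouched.
#'
#' @param s A structure tibble.
#' @param chain,number,icode Identify the residue.
#' @param step Grid step in degrees (default 15).
#' @param max_sweeps Sweep limit (default 6).
#' @param threshold Clash distance in Angstrom.
#' @return The structure with the relaxed side chain.
#' @export
relax_side_chain <- function(s, chain, number, icode = "", step = 15,
                             max_sweeps = 6, threshold = 2.5) {
  res <- residue_atoms(s, chain, number, icode)
  aa3 <- res$resname[1]
  k <- n_chi(aa3)
  if (k == 0) return(s)
  chis <- measure_chis(res)
  bb <- residue_backbone(res)
  own <- s$chain_id == chain & s$resno == number & s$icode == icode
  rest <- as.matrix(s[!own, c("x", "y", "z")])
  score_of <- function(ch) {
    side <- build_side_chain(aa3, bb, ch)
    clash_count(as.matrix(side[, c("x", "y", "z")]), rest, threshold)
  }
  grid <- seq(-180, 180 - step, by = step)
  current <- score_of(chis)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (j in seq_len(k)) {
      cand_vals <- unique(c(chis[j], grid))
      scores <- purrr::map_int(cand_vals, function(v) {
        trial <- chis; trial[j] <- v; score_of(trial)
      })
      best <- order(scores, cand_vals != chis[j], cand_vals)[1]
      # strict improvement only; ties keep the incumbent chi
      if (scores[best] < current) {
        chis[j] <- cand_vals[best]
        current <- scores[best]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  side <- build_side_chain(aa3, bb, chis)
  splice_side_chain(s, chain, number, icode, aa3, side)
}

#' Enumerate plastid-by-nuclear combination identifiers
#'
#' For L lineages there are L^2 combinations; the label puts the plastid
#' (maternal) lineage first, e.g. `E1_W1` models the plastid-encoded variants
#' of E1 together with the nuclear-encoded variants of W1.
#'
#' @param lineages Character vector of lineage labels.
#' @return Tibble with columns `plastid`, `nuclear`, `label`.
#' @export
combination_ids <- function(lineages) {
  stopifnot(length(lineages) >= 1, !anyDuplicated(lineages))
  tidyr::expand_grid(plastid = lineages, nuclear = lineages) |>
    mutate(label = paste(.data$plastid, .data$nuclear, sep = "_"))
}

#' Build one plastid-nuclear combination model
#'
#' Applies the plastid lineage's substitutions to plastid-compartment chains
#' and the nuclear lineage's substitutions to nuclear-compartment chains of
#' the template structure. Substitutions whose target residue is absent from
#' the structure are reported as unapplied rather than silently dropped.
#'
#' @param template A structure tibble (chains annotated via a chain map).
#' @param plastid_lineage,nuclear_lineage Lineage labels.
#' @param subs Long substitution table: columns `lineage`, `gene`,
#'   `ref_number`, `new_aa` (one-letter), as from [build_substitution_sets()].
#' @param chain_map Chain map (path, list or tibble).
#' @param relax Chi-grid relax each rebuilt side chain (default `TRUE`).
#' @return A list of class `combination_model` with elements `label`,
#'   `plastid_lineage`, `nuclear_lineage`, `structure`, `applied`.
#' @export
build_combination_model <- function(template, plastid_lineage, nuclear_lineage,
                                    subs, chain_map, relax = TRUE) {
  cm <- as_chain_map(chain_map)
  subs <- as_tibble(subs)
  pick <- bind_rows(
    filter(subs, .data$lineage == plastid_lineage,
           .data$gene %in% cm$protein[cm$compartment == "plastid"]),
    filter(subs, .data$lineage == nuclear_lineage,
           .data$gene %in% cm$protein[cm$compartment == "nuclear"])
  )
  unknown <- setdiff(
    unique(subs$gene[subs$lineage %in% c(plastid_lineage, nuclear_lineage)]),
    cm$protein
  )
  if (length(unknown) > 0) {
    abort(paste0("substitution targets gene(s) absent from the chain map: ",
                 paste(unknown, collapse = ", ")))
  }
  label <- paste(plastid_lineage, nuclear_lineage, sep = "_")
  if (nrow(pick) == 0) {
    applied <- tibble(gene = character(0), chain_id = character(0),
                      resno = integer(0), old_aa3 = character(0),
                      new_aa3 = character(0), applied = logical(0))
    out <- list(label = label, plastid_lineage = plastid_lineage,
                nuclear_lineage = nuclear_lineage,
                structure = as_structure(template), applied = applied)
    class(out) <- "combination_model"
    return(out)
  }
  pick <- pick |>
    left_join(cm, by = c(gene = "protein")) |>
    mutate(resno = .data$ref_number + .data$offset, icode = "")
  present <- purrr::pmap_lgl(pick[, c("chain_id", "resno")], function(chain_id, resno) {
    any(template$chain_id == chain_id & template$resno == resno & template$icode == "")
  })
  pick$old_aa3 <- NA_character_
  pick$old_aa3[present] <- purrr::pmap_chr(
    pick[present, c("chain_id", "resno")],
    function(chain_id, resno) {
      residue_atoms(template, chain_id, resno)$resname[1]
    }
  )
  targets <- pick[present, c("chain_id", "resno", "icode", "new_aa")]
  structure <- if (nrow(targets) > 0) {
    substitute_residues(template, targets, relax = relax)
  } else {
    as_structure(template)
  }
  applied <- tibble(
    gene = pick$gene, chain_id = pick$chain_id, resno = pick$resno,
    old_aa3 = pick$old_aa3, new_aa3 = aa1_to_aa3(pick$new_aa),
    applied = present
  )
  out <- list(label = label, plastid_lineage = plastid_lineage,
              nuclear_lineage = nuclear_lineage,
              structure = structure, applied = applied)
  class(out) <- "combination_model"
  out
}

#' @export
print.combination_model <- function(x, ...) {
  cat("<combination model ", x$label, ">\n", sep = "")
  cat("  substitutions applied: ", sum(x$applied$applied),
      " of ", nrow(x$applied), "\n", sep = "")
  invisible(x)
}
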