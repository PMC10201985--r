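# Synthetic inputs for every pipeline stage: toy two-chain complexes with
# planted contact geometry, lineage alignments with planted fixed
# differences, and closed-form graph families for centrality oracles.
# Everything is seeded and byte-reproducible.

#' Toy two-chain complex with planted inter-chain contact distances
#'
#' Builds a small dimer whose chains sit far apart (backbones ~40 A), then
#' plants pseudo side-chain atoms so that each requested residue pair's
#' minimal inter-atomic distance equals its target to machine precision.
#' Every unplanned inter-chain residue pair is at least 6 A apart, so the
#' expected inter-chain edge set of the interaction network is exactly the
#' planted pairs whose target lies inside the distance window.
#'
#' Residues are glycine backbones with planted carbon atoms; chemistry
#' realism is not a goal, only controlled contact geometry.
#'
#' @param n_residues Residues per chain.
#' @param contacts Tibble with columns `res_a`, `res_b` (residue numbers on
#'   chain A and B) and `distance` (target minimal distance, 0 < d <= 20);
#'   `NULL` or zero rows plants nothing.
#' @param seed Integer seed for the (small) backbone jitter.
#' @param d_min,d_max Window used to compute the ground-truth edge set.
#' @return List with `structure` (annotated structure tibble; chain A is
#'   protein `ptoy`, compartment plastid; chain B is `ntoy`, nuclear),
#'   `truth` (expected inter-chain edges: `resno_a`, `resno_b`, `distance`),
#'   `contacts`, and `chain_map`.
#' @export
make_toy_dimer <- function(n_residues = 8, contacts = NULL, seed = 1,
                           d_min = 2.5, d_max = 5.0) {
  contacts <- if (is.null(contacts)) {
    tibble(res_a = integer(0), res_b = integer(0), distance = numeric(0))
  } else {
    as_tibble(contacts)
  }
  if (nrow(contacts) > 0) {
    if (any(contacts$distance <= 0 | contacts$distance > 20)) {
      abort("infeasible contact plan: target distances must be in (0, 20]")
    }
    if (any(contacts$res_a < 1 | contacts$res_a > n_residues |
            contacts$res_b < 1 | contacts$res_b > n_residues)) {
      abort("infeasible contact plan: residue index out of range")
    }
    if (anyDuplicated(contacts[, c("res_a", "res_b")])) {
      abort("infeasible contact plan: duplicate residue pair")
    }
  }
  atom_pool <- c("CB", "CG", "CD", "CE", "CZ", "CH")
  backbone_chain <- function(chain, y0, jitter) {
    purrr::map_dfr(seq_len(n_residues), function(i) {
      x0 <- 6 * (i - 1) + jitter[i]
      tibble(
        chain_id = chain, resno = i, icode = "", resname = "GLY",
        atom = c("N", "CA", "C", "O"),
        element = c("N", "C", "C", "O"),
        x = x0 + c(0, 1.46, 2.90, 3.40),
        y = y0 + c(0, 0.20, 0, 1.10),
        z = 0,
        occupancy = 1, altloc = ""
      )
    })
  }
  jit <- withr::with_seed(seed, list(a = runif(n_residues, -0.3, 0.3),
                                     b = runif(n_residues, -0.3, 0.3)))
  s <- bind_rows(backbone_chain("A", 0, jit$a), backbone_chain("B", 40, jit$b))
  if (nrow(contacts) > 0) {
    planted <- purrr::map_dfr(seq_len(nrow(contacts)), function(c_idx) {
      cc <- contacts[c_idx, ]
      lane <- 20 * c_idx
      cx <- 3 * c_idx
      used_a <- sum(contacts$res_a[seq_len(c_idx)] == cc$res_a)
      used_b <- sum(contacts$res_b[seq_len(c_idx)] == cc$res_b)
      if (used_a > length(atom_pool) || used_b > length(atom_pool)) {
        abort("infeasible contact plan: too many contacts on one residue")
      }
      tibble(
        chain_id = c("A", "B"),
        resno = c(cc$res_a, cc$res_b), icode = "", resname = "GLY",
        atom = c(atom_pool[used_a], atom_pool[used_b]),
        element = "C",
        x = cx, y = c(10, 10 + cc$distance), z = lane,
        occupancy = 1, altloc = ""
      )
    })
    s <- bind_rows(s, planted)
  }
  s$standard <- TRUE
  chain_map <- tibble(
    protein = c("ptoy", "ntoy"), chain_id = c("A", "B"),
    compartment = c("plastid", "nuclear"), offset = 0L
  )
  s <- annotate_chains(s, chain_map)
  truth <- contacts |>
    filter(.data$distance >= d_min, .data$distance <= d_max) |>
    transmute(resno_a = as.integer(.data$res_a), resno_b = as.integer(.data$res_b),
              distance = .data$distance) |>
    arrange(.data$resno_a, .data$resno_b)
  list(structure = s, truth = truth, contacts = contacts, chain_map = chain_map)
}

#' Random feasible contact plan for the toy dimer
#'
#' Samples distinct residue pairs with target distances spanning below,
#' inside and above the default interaction window, so monotonicity and
#' boundary behavior get exercised.
#'
#' @param n_residues Residues per chain.
#' @param n_contacts Number of planted pairs.
#' @param seed Integer seed.
#' @return A contacts tibble for [make_toy_dimer()].
#' @export
random_toy_plan <- function(n_residues = 8, n_contacts = 5, seed = 1) {
  withr::with_seed(seed, {
    pairs <- tidyr::expand_grid(res_a = seq_len(n_residues),
                                res_b = seq_len(n_residues))
    pick <- pairs[sample(nrow(pairs), min(n_contacts, nrow(pairs))), ]
    pick$distance <- round(runif(nrow(pick), 1.5, 7.0), 2)
    pick
  })
}

#' Planted per-lineage alignment with known fixed differences
#'
#' Generates an aligned amino-acid dataset for several lineages plus a
#' reference sequence, with differentially fixed substitutions planted at
#' chosen columns, and returns the exact truth table a variant caller should
#' recover. Optional decoys exercise the exclusion rules: within-lineage
#' polymorphic columns and columns with an alignment gap in a sample
#' sequence are never truth rows; columns where the reference itself has a
#' gap stay in the truth but are unmappable to reference numbering.
#'
#' @param lineages Lineage labels (default the four study lineages).
#' @param n_per_lineage Sequences per lineage.
#' @param length Alignment length (columns).
#' @param planted Tibble with columns `position` and one amino-acid column
#'   per lineage (all lineages required); `NULL` plants nothing.
#' @param n_polymorphic Number of decoy columns made polymorphic within the
#'   first lineage (needs `n_per_lineage >= 2`).
#' @param n_gap_cols Number of decoy columns given a gap in one sample.
#' @param ref_gap_cols Columns where the reference sequence has a gap.
#' @param gene Gene name carried through the outputs.
#' @param seed Integer seed.
#' @return List with `alignment` (tibble `gene`, `seq_id`, `lineage`,
#'   `sequence`; the reference row has lineage `"reference"`) and `truth`
#'   (tibble `gene`, `column`, `ref_number`, `ref_aa`, plus one column per
#'   lineage).
#' @export
make_lineage_alignment <- function(lineages = c("E1", "W1", "W2", "W3"),
                                   n_per_lineage = 3, length = 60,
                                   planted = NULL, n_polymorphic = 0,
                                   n_gap_cols = 0, ref_gap_cols = integer(0),
                                   gene = "rps21", seed = 1) {
  aa <- aa_codes()$aa1
  planted <- if (is.null(planted)) {
    tibble(position = integer(0))
  } else {
    as_tibble(planted)
  }
  if (nrow(planted) > 0) {
    missing_lin <- setdiff(lineages, names(planted))
    if (length(missing_lin) > 0) {
      abort(paste0("planted map missing lineage(s): ",
                   paste(missing_lin, collapse = ", ")))
    }
    if (any(planted$position < 1 | planted$position > length)) {
      abort("planted position outside the alignment")
    }
  }
  withr::with_seed(seed, {
    ref <- sample(aa, length, replace = TRUE)
    base <- ref
    if (length(ref_gap_cols) > 0) {
      ref[ref_gap_cols] <- "-"
      base[ref_gap_cols] <- sample(aa, length(ref_gap_cols), replace = TRUE)
    }
    seqs <- tidyr::expand_grid(lineage = lineages, rep = seq_len(n_per_lineage))
    seq_chars <- purrr::map(seq_len(nrow(seqs)), function(i) base)
    for (p in seq_len(nrow(planted))) {
      col <- planted$position[p]
      for (li in lineages) {
        rows <- which(seqs$lineage == li)
        for (r in rows) seq_chars[[r]][col] <- planted[[li]][p]
      }
    }
    taken <- planted$position
    free <- setdiff(seq_len(length), c(taken, ref_gap_cols))
    if (n_polymorphic > 0) {
      if (n_per_lineage < 2) abort("polymorphic decoys need n_per_lineage >= 2")
      poly_cols <- sample(free, n_polymorphic)
      free <- setdiff(free, poly_cols)
      first_rows <- which(seqs$lineage == lineages[1])
      for (col in poly_cols) {
        cur <- seq_chars[[first_rows[1]]][col]
        seq_chars[[first_rows[1]]][col] <- sample(setdiff(aa, cur), 1)
      }
    }
    if (n_gap_cols > 0) {
      gap_cols <- sample(free, n_gap_cols)
      victim <- sample(seq_len(nrow(seqs)), n_gap_cols, replace = TRUE)
      for (i in seq_along(gap_cols)) {
        seq_chars[[victim[i]]][gap_cols[i]] <- "-"
      }
    }
    alignment <- bind_rows(
      tibble(gene = gene, seq_id = "Spinacia_oleracea", lineage = "reference",
             sequence = paste(ref, collapse = "")),
      tibble(gene = gene,
             seq_id = paste0(seqs$lineage, "_", seqs$rep),
             lineage = seqs$lineage,
             sequence = purrr::map_chr(seq_chars, paste, collapse = ""))
    )
    truth <- if (nrow(planted) == 0) {
      empty <- tibble(gene = character(0), column = integer(0),
                      ref_number = integer(0), ref_aa = character(0))
      for (li in lineages) empty[[li]] <- character(0)
      empty
    } else {
      ref_no <- cumsum(ref != "-")
      tt <- planted |>
        mutate(
          gene = gene, column = as.integer(.data$position),
          ref_number = ifelse(ref[.data$position] == "-", NA_integer_,
                              ref_no[.data$position]),
          ref_aa = ifelse(ref[.data$position] == "-", NA_character_,
                          ref[.data$position])
        )
      # differentially fixed = lineage amino acids not all identical
      lin_mat <- as.matrix(tt[, lineages])
      differs <- apply(lin_mat, 1, function(r) length(unique(r)) > 1)
      tt <- tt[differs, c("gene", "column", "ref_number", "ref_aa", lineages)]
      arrange(tt, .data$column)
    }
    list(alignment = alignment, truth = truth)
  })
}

#' Write a lineage alignment to per-gene FASTA
#'
#' Sequence names encode the lineage as `lineage|sample`.
#'
#' @param alignment Alignment tibble as produced by
#'   [make_lineage_alignment()].
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_lineage_fasta <- function(alignment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::map_chr(unique(alignment$gene), function(g) {
    sub <- alignment[alignment$gene == g, ]
    set <- Biostrings::AAStringSet(sub$sequence)
    names(set) <- paste0(sub$lineage, "|", sub$seq_id)
    path <- file.path(dir, paste0(g, ".fasta"))
    Biostrings::writeXStringSet(set, path)
    path
  })
  invisible(paths)
}

#' Read per-gene lineage FASTA files
#'
#' @param paths FASTA files (one gene per file; gene name from the file
#'   name); sequence ids must be `lineage|sample`.
#' @return Alignment tibble with `gene`, `seq_id`, `lineage`, `sequence`.
#' @export
read_lineage_alignment <- function(paths) {
  purrr::map_dfr(paths, function(p) {
    set <- Biostrings::readAAStringSet(p)
    ids <- names(set)
    if (!all(grepl("\\|", ids))) {
      abort(paste0("sequence ids in ", p, " must be 'lineage|sample'"))
    }
    tibble(
      gene = sub("\\.(fa|fasta)$", "", basename(p)),
      seq_id = sub("^[^|]*\\|", "", ids),
      lineage = sub("\\|.*$", "", ids),
      sequence = unname(as.character(set))
    )
  })
}

#' Closed-form graph fixtures for centrality oracles
#'
#' @param kind `"path"`, `"star"`, `"complete"` or `"two_cliques_bridge"`
#'   (two equal cliques joined through a single articulation node; requires
#'   odd `n >= 5`).
#' @param n Number of nodes (>= 2).
#' @return A `rin` object with dummy residue labels and edge distances.
#' @export
make_graph_fixture <- function(kind = c("path", "star", "complete",
                                        "two_cliques_bridge"), n) {
  kind <- match.arg(kind)
  stopifnot(n >= 2)
  edges <- switch(
    kind,
    path = tibble(a = seq_len(n - 1), b = seq_len(n - 1) + 1L),
    star = tibble(a = 1L, b = 2:n),
    complete = {
      pr <- utils::combn(n, 2)
      tibble(a = pr[1, ], b = pr[2, ])
    },
    two_cliques_bridge = {
      if (n < 5 || n %% 2 == 0) abort("two_cliques_bridge needs odd n >= 5")
      k <- (n - 1) / 2
      clique <- function(members) {
        if (length(members) < 2) return(tibble(a = integer(0), b = integer(0)))
        pr <- utils::combn(members, 2)
        tibble(a = pr[1, ], b = pr[2, ])
      }
      bridge <- k + 1L
      bind_rows(clique(seq_len(k)), clique(seq(k + 2L, n)),
                tibble(a = bridge, b = c(1L, k + 2L)))
    }
  )
  nodes <- tibble(
    node = paste0("A:", seq_len(n)), chain_id = "A", resno = seq_len(n),
    icode = "", resname = "GLY", protein = "toy", compartment = "plastid"
  )
  out <- list(
    nodes = nodes,
    edges = tibble(node_a = paste0("A:", pmin(edges$a, edges$b)),
                   node_b = paste0("A:", pmax(edges$a, edges$b)),
                   distance = 4.0) |>
      arrange(.data$node_a, .data$node_b),
    window = c(d_min = 2.5, d_max = 5.0)
  )
  class(out) <- "rin"
  out
}

#' The bridge node of a two-clique fixture
#' @param n Node count of the fixture.
#' @return Node id of the articulation node.
#' @export
bridge_node <- function(n) paste0("A:", (n - 1) / 2 + 1)
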