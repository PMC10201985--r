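# Residue interaction networks: nodes are residues, an undirected edge links
# two residues whose minimal any-atom distance falls inside the window
# (default 2.5-5.0 A, both bounds inclusive). Pairs closer than the lower
# bound are excluded exactly as stated by the rule (presumed covalent or
# clashing).

node_id <- function(chain_id, resno, icode) {
  paste0(chain_id, ":", resno, ifelse(icode == "", "", icode))
}

#' Build a residue interaction network
#'
#' Edge (A, B) is present iff the minimal distance over all atom pairs of A
#' and B lies in `[d_min, d_max]` (inclusive). Covalently adjacent residues
#' get no special-casing. A spatial grid at `d_max` resolution keeps the scan
#' near-linear in atoms; the result is identical to a brute-force all-pairs
#' scan.
#'
#' @param s A structure tibble with >= 2 residues.
#' @param d_min,d_max Distance window in Angstrom (default 2.5 and 5.0).
#' @return An object of class `rin`: list with `nodes` (one row per residue:
#'   `node`, `chain_id`, `resno`, `icode`, `resname`, `protein`,
#'   `compartment`), `edges` (`node_a`, `node_b`, `distance`) and `window`.
#' @export
build_rin <- function(s, d_min = 2.5, d_max = 5.0) {
  stopifnot(d_min > 0, d_min < d_max)
  s <- as_structure(s)
  nodes <- s |>
    distinct(.data$chain_id, .data$resno, .data$icode, .data$resname,
             .data$protein, .data$compartment) |>
    arrange(.data$chain_id, .data$resno, .data$icode) |>
    mutate(node = node_id(.data$chain_id, .data$resno, .data$icode), .before = 1)
  if (nrow(nodes) < 2) abort("structure must contain at least 2 residues")
  atom_node <- match(
    node_id(s$chain_id, s$resno, s$icode), nodes$node
  )
  xyz <- as.matrix(s[, c("x", "y", "z")])
  # spatial binning at d_max: all atom pairs within d_max share neighboring
  # cells, so per-pair minima at or below d_max are exact
  cell <- floor(sweep(xyz, 2, rep(d_max, 3), "/"))
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cell_atoms <- split(seq_len(nrow(xyz)), key)
  cells <- do.call(rbind, strsplit(names(cell_atoms), " "))
  cells <- matrix(as.numeric(cells), ncol = 3)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  best <- new.env(parent = emptyenv())
  record <- function(ia, ib, d) {
    na <- atom_node[ia]; nb <- atom_node[ib]
    keep <- na != nb
    if (!any(keep)) return(invisible())
    na <- na[keep]; nb <- nb[keep]; d <- d[keep]
    lo <- pmin(na, nb); hi <- pmax(na, nb)
    k <- paste0(lo, "_", hi)
    for (u in unique(k)) {
      dmin <- min(d[k == u])
      old <- best[[u]]
      if (is.null(old) || dmin < old) assign(u, dmin, envir = best)
    }
  }
  key_index <- seq_along(cell_atoms)
  names(key_index) <- names(cell_atoms)
  for (ci in seq_along(cell_atoms)) {
    a_idx <- cell_atoms[[ci]]
    for (o in seq_len(nrow(offsets))) {
      nb_key <- paste(cells[ci, 1] + offsets[o, 1],
                      cells[ci, 2] + offsets[o, 2],
                      cells[ci, 3] + offsets[o, 3])
      cj <- key_index[nb_key]
      if (is.na(cj) || cj < ci) next
      b_idx <- cell_atoms[[cj]]
      if (cj == ci) {
        if (length(a_idx) < 2) next
        pr <- utils::combn(a_idx, 2)
        ia <- pr[1, ]; ib <- pr[2, ]
      } else {
        g <- expand.grid(ia = a_idx, ib = b_idx)
        ia <- g$ia; ib <- g$ib
      }
      d <- sqrt(rowSums((xyz[ia, , drop = FALSE] - xyz[ib, , drop = FALSE])^2))
      near <- d <= d_max
      if (any(near)) record(ia[near], ib[near], d[near])
    }
  }
  keys <- ls(best)
  if (length(keys) == 0) {
    edges <- tibble(node_a = character(0), node_b = character(0),
                    distance = numeric(0))
  } else {
    parts <- do.call(rbind, strsplit(keys, "_"))
    edges <- tibble(
      ia = as.integer(parts[, 1]), ib = as.integer(parts[, 2]),
      distance = purrr::map_dbl(keys, ~ best[[.x]])
    ) |>
      filter(.data$distance >= d_min, .data$distance <= d_max) |>
      transmute(node_a = nodes$node[.data$ia], node_b = nodes$node[.data$ib],
                distance = .data$distance) |>
      arrange(.data$node_a, .data$node_b)
  }
  out <- list(nodes = nodes, edges = edges, window = c(d_min = d_min, d_max = d_max))
  class(out) <- "rin"
  out
}

#' @export
print.rin <- function(x, ...) {
  cat("<residue interaction network: ", nrow(x$nodes), " residues, ",
      nrow(x$edges), " edges, window [", x$window[1], ", ", x$window[2],
      "] A>\n", sep = "")
  invisible(x)
}

#' Interface edges between two proteins
#'
#' @param g A `rin` object.
#' @param protein_a,protein_b Gene names (order-insensitive).
#' @return Edge tibble restricted to pairs with one endpoint on each protein,
#'   with endpoint annotation columns.
#' @export
interface_edges <- function(g, protein_a, protein_b) {
  known <- unique(g$nodes$protein[!is.na(g$nodes$protein)])
  unknown <- setdiff(c(protein_a, protein_b), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown protein(s): ", paste(unknown, collapse = ", "),
                 "; available: ", paste(known, collapse = ", ")))
  }
  prot <- setNames(g$nodes$protein, g$nodes$node)
  pa <- prot[g$edges$node_a]
  pb <- prot[g$edges$node_b]
  hit <- (pa == protein_a & pb == protein_b) | (pa == protein_b & pb == protein_a)
  edges <- g$edges[hit & !is.na(hit), ]
  # orient so protein_a comes first
  flip <- prot[edges$node_a] != protein_a
  tmp <- edges$node_a[flip]
  edges$node_a[flip] <- edges$node_b[flip]
  edges$node_b[flip] <- tmp
  info <- g$nodes[, c("node", "resno", "resname", "protein")]
  edges |>
    left_join(info, by = c(node_a = "node")) |>
    rename(resno_a = "resno", resname_a = "resname", protein_a = "protein") |>
    left_join(info, by = c(node_b = "node")) |>
    rename(resno_b = "resno", resname_b = "resname", protein_b = "protein") |>
    arrange(.data$resno_a, .data$resno_b)
}

#' Export a RIN edge list to TSV
#'
#' One row per edge with both residue identifiers and the minimal distance
#' (3 decimals); rows sorted by chain and residue number, so repeated exports
#' are byte-identical.
#'
#' @param g A `rin` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_edge_list <- function(g, path) {
  info <- g$nodes[, c("node", "chain_id", "resno", "icode", "resname")]
  out <- g$edges |>
    left_join(info, by = c(node_a = "node")) |>
    rename(chain_a = "chain_id", resno_a = "resno", icode_a = "icode",
           resname_a = "resname") |>
    left_join(info, by = c(node_b = "node")) |>
    rename(chain_b = "chain_id", resno_b = "resno", icode_b = "icode",
           resname_b = "resname") |>
    arrange(.data$chain_a, .data$resno_a, .data$chain_b, .data$resno_b) |>
    mutate(distance = sprintf("%.3f", .data$distance)) |>
    select("node_a", "chain_a", "resno_a", "icode_a", "resname_a",
           "node_b", "chain_b", "resno_b", "icode_b", "resname_b", "distance")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back an exported edge list
#'
#' @param path TSV written by [export_edge_list()].
#' @return Edge tibble with `node_a`, `node_b`, `distance`.
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    transmute(node_a = .data$node_a, node_b = .data$node_b,
              distance = as.numeric(.data$distance))
}

#' Convert a RIN to an igraph graph
#'
#' Edge minimal distances travel as the `distance` edge attribute; path-based
#' centralities treat the graph as unweighted.
#'
#' @param g A `rin` object.
#' @return An `igraph` graph including isolated nodes.
#' @export
rin_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("node_a", "node_b", "distance")],
    directed = FALSE,
    vertices = g$nodes
  )
  ig
}
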