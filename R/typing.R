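# Interface contact typing. The published calls were made by visual
# inspection; the rules here are a deterministic geometric rendering with
# config-exposed thresholds, applied in fixed priority order.

#' Typing thresholds
#'
#' @param salt_bridge Max distance (A) between a charged side-chain nitrogen
#'   (Arg/Lys/His) and a carboxylate oxygen (Asp/Glu). Default 4.0.
#' @param h_bond Max heavy-atom donor/acceptor N/O distance. Default 3.5
#'   (no hydrogen positions are assumed, so no angle term).
#' @param hydrophobic Max carbon-carbon side-chain contact distance. Default
#'   4.5.
#' @param window Interaction window used by the polar rule (defaults to the
#'   RIN window).
#' @return Named list of thresholds.
#' @export
typing_thresholds <- function(salt_bridge = 4.0, h_bond = 3.5,
                              hydrophobic = 4.5, window = c(2.5, 5.0)) {
  list(salt_bridge = salt_bridge, h_bond = h_bond,
       hydrophobic = hydrophobic, window = window)
}

charged_n <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"))
carboxylate_o <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
hydrophobic_res <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "PRO", "TRP")
# side-chain carbons not bonded to N or O
apolar_carbons <- list(
  ALA = "CB", ARG = c("CB", "CG"), ASN = "CB", ASP = "CB", CYS = "CB",
  GLN = c("CB", "CG"), GLU = c("CB", "CG"), GLY = character(0), HIS = "CB",
  ILE = c("CB", "CG1", "CG2", "CD1"), LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD"), MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG"), SER = character(0), THR = "CG2",
  TRP = c("CB", "CG", "CD2", "CE3", "CZ3", "CH2", "CZ2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  VAL = c("CB", "CG1", "CG2")
)

pair_distances <- function(res_a, res_b) {
  a <- as.matrix(res_a[, c("x", "y", "z")])
  b <- as.matrix(res_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Classify the interaction between two residues
#'
#' Deterministic priority rules (first match wins):
#'
#' 1. **salt bridge** - side-chain charged N of Arg/Lys/His within the salt
#'    bridge threshold of a side-chain carboxylate O of Asp/Glu;
#' 2. **hydrogen bond** - any N/O heavy-atom pair within the h-bond
#'    threshold;
#' 3. **hydrophobic** - any side-chain carbon-carbon contact within the
#'    hydrophobic threshold where both residues are apolar types or both
#'    atoms are apolar carbons;
#' 4. **polar** - any contact inside the interaction window involving at
#'    least one N/O not caught by rule 2;
#' 5. **none** otherwise.
#'
#' Symmetric in its arguments.
#'
#' @param res_a,res_b Atom tibbles of the two residues.
#' @param thresholds See [typing_thresholds()].
#' @return One of `"salt_bridge"`, `"h_bond"`, `"hydrophobic"`, `"polar"`,
#'   `"none"`.
#' @export
classify_interaction <- function(res_a, res_b, thresholds = typing_thresholds()) {
  if (nrow(res_a) == 0 || nrow(res_b) == 0) abort("residue with no atoms")
  d <- pair_distances(res_a, res_b)
  aa_a <- res_a$resname[1]
  aa_b <- res_b$resname[1]

  charged_sel <- function(res, aa) res$atom %in% (charged_n[[aa]] %||% character(0))
  carbox_sel <- function(res, aa) res$atom %in% (carboxylate_o[[aa]] %||% character(0))
  sb <- function(ra, aa_ra, rb, aa_rb, dmat) {
    i <- charged_sel(ra, aa_ra); j <- carbox_sel(rb, aa_rb)
    any(i) && any(j) && min(dmat[i, j, drop = FALSE]) <= thresholds$salt_bridge
  }
  if (sb(res_a, aa_a, res_b, aa_b, d) || sb(res_b, aa_b, res_a, aa_a, t(d))) {
    return("salt_bridge")
  }

  no_a <- res_a$element %in% c("N", "O")
  no_b <- res_b$element %in% c("N", "O")
  if (any(no_a) && any(no_b) &&
      min(d[no_a, no_b, drop = FALSE]) <= thresholds$h_bond) {
    return("h_bond")
  }

  side_c_a <- res_a$element == "C" & !(res_a$atom %in% c("C", "CA"))
  side_c_b <- res_b$element == "C" & !(res_b$atom %in% c("C", "CA"))
  if (any(side_c_a) && any(side_c_b)) {
    dcc <- d[side_c_a, side_c_b, drop = FALSE]
    close_cc <- dcc <= thresholds$hydrophobic
    if (any(close_cc)) {
      both_hydrophobic <- aa_a %in% hydrophobic_res && aa_b %in% hydrophobic_res
      ap_a <- res_a$atom[side_c_a] %in% (apolar_carbons[[aa_a]] %||% character(0))
      ap_b <- res_b$atom[side_c_b] %in% (apolar_carbons[[aa_b]] %||% character(0))
      apolar_pair <- outer(ap_a, ap_b, "&")
      if (both_hydrophobic || any(close_cc & apolar_pair)) {
        return("hydrophobic")
      }
    }
  }

  involves_no <- outer(no_a, rep(TRUE, nrow(res_b)), "&") |
    outer(rep(TRUE, nrow(res_a)), no_b, "&")
  in_window <- d >= thresholds$window[1] & d <= thresholds$window[2]
  if (any(in_window & involves_no)) {
    return("polar")
  }
  "none"
}

#' Type every edge of an interface
#'
#' @param s The structure the network was built from.
#' @param edges Interface edge tibble from [interface_edges()].
#' @param thresholds See [typing_thresholds()].
#' @return The edges with a `type` column.
#' @export
type_interface <- function(s, edges, thresholds = typing_thresholds()) {
  split_node <- function(node) {
    chain <- sub(":.*$", "", node)
    rest <- sub("^[^:]*:", "", node)
    resno <- as.integer(sub("[^0-9-].*$", "", rest))
    icode <- sub("^-?[0-9]+", "", rest)
    list(chain = chain, resno = resno, icode = icode)
  }
  edges$type <- purrr::map2_chr(edges$node_a, edges$node_b, function(na, nb) {
    a <- split_node(na); b <- split_node(nb)
    classify_interaction(
      residue_atoms(s, a$chain, a$resno, a$icode),
      residue_atoms(s, b$chain, b$resno, b$icode),
      thresholds
    )
  })
  edges
}

#' Compare typed contact maps of a reference and a mutant model
#'
#' Pairs present only in the reference are losses, pairs present only in the
#' mutant are gains, pairs in both keep `unchanged` or become `type_change`.
#'
#' @param wt,mut Typed contact tibbles with columns `node_a`, `node_b`,
#'   `type` (as from [type_interface()]), keyed by residue pair.
#' @return Interaction-record tibble: `node_a`, `node_b`, `before`, `after`,
#'   `category`.
#' @export
compare_models <- function(wt, mut) {
  key <- function(x) paste(pmin(x$node_a, x$node_b), pmax(x$node_a, x$node_b))
  wt <- as_tibble(wt); mut <- as_tibble(mut)
  wt$.key <- key(wt); mut$.key <- key(mut)
  if (anyDuplicated(wt$.key) || anyDuplicated(mut$.key)) {
    abort("duplicate residue pair keys in contact map")
  }
  all_keys <- union(wt$.key, mut$.key)
  before <- wt$type[match(all_keys, wt$.key)]
  after <- mut$type[match(all_keys, mut$.key)]
  before[is.na(before)] <- "none"
  after[is.na(after)] <- "none"
  src <- bind_rows(wt, mut)
  pick <- src[match(all_keys, src$.key), c("node_a", "node_b")]
  out <- tibble(
    node_a = pick$node_a, node_b = pick$node_b,
    before = before, after = after,
    category = purrr::map2_chr(before, after, categorize_record)
  )
  arrange(out, .data$node_a, .data$node_b)
}

# Accept both the comparison output naming (before/after) and the fixture
# naming (type_before/type_after).
normalize_records <- function(records) {
  records <- as_tibble(records)
  if (!"before" %in% names(records) && "type_before" %in% names(records)) {
    records$before <- records$type_before
  }
  if (!"after" %in% names(records) && "type_after" %in% names(records)) {
    records$after <- records$type_after
  }
  if (!all(c("before", "after") %in% names(records))) {
    abort("records need before/after (or type_before/type_after) columns")
  }
  records
}

# Category of one record. `after` may carry lineage-dependent variants
# separated by "/": a record counts as loss (gain) if any variant loses
# (gains) the contact, matching the published tally.
categorize_record <- function(before, after) {
  variants <- strsplit(after, "/", fixed = TRUE)[[1]]
  per <- vapply(variants, function(v) {
    if (before == v) "unchanged"
    else if (before != "none" && v == "none") "loss"
    else if (before == "none" && v != "none") "gain"
    else "type_change"
  }, character(1))
  if (all(per == "unchanged")) "unchanged"
  else if (any(per == "loss")) "loss"
  else if (any(per == "gain")) "gain"
  else "type_change"
}

#' Tally interaction-change categories
#'
#' @param records Tibble with `before`/`after` (and optionally `category`)
#'   columns.
#' @return One-row tibble: `loss`, `gain`, `type_change`, `unchanged`,
#'   `total`.
#' @export
categorize_changes <- function(records) {
  records <- normalize_records(records)
  if (!"category" %in% names(records)) {
    records$category <- purrr::map2_chr(records$before, records$after,
                                        categorize_record)
  }
  tibble(
    loss = sum(records$category == "loss"),
    gain = sum(records$category == "gain"),
    type_change = sum(records$category == "type_change"),
    unchanged = sum(records$category == "unchanged"),
    total = nrow(records)
  )
}

#' Per-type tally of losses or gains
#'
#' Losses are counted by the interaction type before mutation, gains by the
#' (non-`none`) type after mutation.
#'
#' @param records Record tibble with `before`, `after` and `category`.
#' @param category `"loss"` or `"gain"`.
#' @return Tibble `type`, `n` over the four interaction types.
#' @export
subtype_tally <- function(records, category = c("loss", "gain")) {
  category <- match.arg(category)
  records <- normalize_records(records)
  if (!"category" %in% names(records)) {
    records$category <- purrr::map2_chr(records$before, records$after,
                                        categorize_record)
  }
  sub <- records[records$category == category, ]
  types <- if (category == "loss") {
    sub$before
  } else {
    purrr::map_chr(strsplit(sub$after, "/", fixed = TRUE), function(v) {
      nz <- setdiff(v, "none")
      if (length(nz) == 0) "none" else nz[1]
    })
  }
  all_types <- c("h_bond", "salt_bridge", "hydrophobic", "polar")
  tibble(type = all_types,
         n = vapply(all_types, function(t) sum(types == t), integer(1),
                    USE.NAMES = FALSE))
}
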