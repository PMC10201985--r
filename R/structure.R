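#' Read a chain map
#'
#' A chain map links protein (gene) names to chain identifiers in a coordinate
#' file and records the encoding compartment of each gene. It is a small YAML
#' or JSON document of the form
#'
#' ```yaml
#' rps11: {chain: "N", compartment: plastid}
#' rps21: {chain: "X", compartment: nuclear, offset: 0}
#' ```
#'
#' The optional per-gene `offset` reconciles sequence numbering with the
#' deposited structure's author numbering (added to sequence-derived residue
#' numbers; default 0).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a named list with
#'   the same shape.
#' @return A tibble with columns `protein`, `chain_id`, `compartment`,
#'   `offset`.
#' @export
read_chain_map <- function(path) {
  raw <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  if (length(raw) == 0 || is.null(names(raw))) {
    abort("chain map must be a named mapping of protein -> {chain, compartment}")
  }
  map <- purrr::imap_dfr(raw, function(entry, protein) {
    tibble(
      protein     = protein,
      chain_id    = as.character(entry$chain %||% entry$chain_id),
      compartment = as.character(entry$compartment %||% "other"),
      offset      = as.integer(entry$offset %||% 0L)
    )
  })
  bad <- setdiff(map$compartment, c("plastid", "nuclear", "rna", "other"))
  if (length(bad) > 0) {
    abort(paste0("unknown compartment(s) in chain map: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(map$protein)) abort("duplicate protein names in chain map")
  map
}

as_chain_map <- function(chain_map) {
  if (is.null(chain_map)) return(NULL)
  if (is.data.frame(chain_map)) {
    stopifnot(all(c("protein", "chain_id", "compartment") %in% names(chain_map)))
    cm <- as_tibble(chain_map)
    if (!"offset" %in% names(cm)) cm$offset <- 0L
    return(cm)
  }
  read_chain_map(chain_map)
}

#' Standard three-letter and one-letter amino-acid codes
#' @keywords internal
aa_codes <- function() {
  tibble(
    aa3 = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL"),
    aa1 = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V")
  )
}

aa1_to_aa3 <- function(aa1) {
  codes <- aa_codes()
  out <- codes$aa3[match(toupper(aa1), codes$aa1)]
  if (anyNA(out)) abort(paste0("unknown one-letter amino acid: ",
                               paste(aa1[is.na(out)], collapse = ", ")))
  out
}

aa3_to_aa1 <- function(aa3) {
  codes <- aa_codes()
  codes$aa1[match(toupper(aa3), codes$aa3)]
}

structure_columns <- c(
  "chain_id", "protein", "compartment", "resno", "icode", "resname",
  "atom", "element", "x", "y", "z", "occupancy", "altloc", "standard"
)

#' Validate an atom-level structure tibble
#'
#' A structure is a tidy atom table: one row per atom with columns `chain_id`,
#' `protein`, `compartment`, `resno`, `icode`, `resname`, `atom`, `element`,
#' `x`, `y`, `z`, `occupancy`, `altloc`, `standard`. All coordinate values
#' must be finite and occupancies in \[0, 1\].
#'
#' @param s A data frame of atoms.
#' @return The validated structure as a tibble.
#' @export
as_structure <- function(s) {
  s <- as_tibble(s)
  missing_cols <- setdiff(structure_columns, names(s))
  if (length(missing_cols) > 0) {
    abort(paste0("structure is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(is.finite(c(s$x, s$y, s$z)))) abort("non-finite atom coordinates")
  if (any(s$occupancy < 0 | s$occupancy > 1, na.rm = TRUE)) {
    abort("occupancy outside [0, 1]")
  }
  s[structure_columns]
}

derive_element <- function(atom_name) {
  first <- substr(gsub("[0-9']", "", atom_name), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, "C")
}

#' Read a structure from PDB or mmCIF
#'
#' Parses a coordinate file into a tidy atom table. Waters and non-polymer
#' ligands (HETATM records) are excluded; for alternate locations only the
#' highest-occupancy conformer is kept (ties broken by altloc letter order).
#' Chains are annotated with protein name and encoding compartment from the
#' chain map; unmapped chains get `compartment = "other"`.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (from extension), `"pdb"` or `"cif"`.
#' @param chain_map Optional chain map (path, list or tibble); see
#'   [read_chain_map()].
#' @return A structure tibble (see [as_structure()]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), chain_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) abort(paste0("could not parse ", path, " as ", format, ": ",
                                     conditionMessage(e)))
  )
  at <- as_tibble(parsed$atom)
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ]
  if (nrow(at) == 0) abort(paste0("no polymer atoms found in ", path))
  s <- tibble(
    chain_id  = as.character(at$chain),
    resno     = as.integer(at$resno),
    icode     = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resname   = toupper(as.character(at$resid)),
    atom      = as.character(at$elety),
    element   = ifelse(is.na(at$elesy) | at$elesy == "",
                       derive_element(at$elety), toupper(as.character(at$elesy))),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc    = ifelse(is.na(at$alt), "", as.character(at$alt))
  )
  # alternate locations: keep the highest-occupancy conformer per atom
  s <- s |>
    arrange(.data$chain_id, .data$resno, .data$icode, .data$atom,
            desc(.data$occupancy), .data$altloc) |>
    distinct(.data$chain_id, .data$resno, .data$icode, .data$atom, .keep_all = TRUE)
  s$standard <- s$resname %in% aa_codes()$aa3
  annotate_chains(s, as_chain_map(chain_map))
}

annotate_chains <- function(s, chain_map) {
  if (is.null(chain_map)) {
    s$protein <- NA_character_
    s$compartment <- "other"
    return(as_structure(s))
  }
  missing_chain <- setdiff(chain_map$chain_id, unique(s$chain_id))
  if (length(missing_chain) > 0) {
    abort(paste0("chain map references chain id(s) absent from the file: ",
                 paste(missing_chain, collapse = ", ")))
  }
  s$protein <- chain_map$protein[match(s$chain_id, chain_map$chain_id)]
  s$compartment <- chain_map$compartment[match(s$chain_id, chain_map$chain_id)]
  s$compartment[is.na(s$compartment)] <- "other"
  as_structure(s)
}

#' Restrict a structure to named proteins
#'
#' @param s A structure tibble with chain annotation.
#' @param proteins Character vector of gene names (as in the chain map).
#' @return The sub-structure containing exactly the requested chains,
#'   coordinates unchanged.
#' @export
select_chains <- function(s, proteins) {
  s <- as_structure(s)
  available <- unique(s$protein[!is.na(s$protein)])
  unknown <- setdiff(proteins, available)
  if (length(unknown) > 0) {
    abort(paste0("unknown protein(s): ", paste(unknown, collapse = ", "),
                 "; available: ", paste(available, collapse = ", ")))
  }
  filter(s, .data$protein %in% proteins)
}

#' Extract the atoms of one residue
#'
#' @param s A structure tibble.
#' @param chain Chain identifier.
#' @param number Residue number (author numbering).
#' @param icode Insertion code (default empty).
#' @return Atom tibble for the residue; error if absent.
#' @export
residue_atoms <- function(s, chain, number, icode = "") {
  res <- filter(s, .data$chain_id == chain, .data$resno == number,
                .data$icode == !!icode)
  if (nrow(res) == 0) {
    abort(paste0("residue ", chain, ":", number, icode, " not found"))
  }
  res
}

#' Minimal inter-atomic distance between two residues
#'
#' Implements the distance primitive of the interaction rule: the minimum
#' over all atom pairs of the Euclidean distance, in Angstrom. Symmetric in
#' its arguments.
#'
#' @param res_a,res_b Atom tibbles (rows of a structure), each with >= 1 atom.
#' @return Minimal distance in Angstrom.
#' @export
min_residue_distance <- function(res_a, res_b) {
  if (nrow(res_a) == 0 || nrow(res_b) == 0) abort("residue with no atoms")
  a <- as.matrix(res_a[, c("x", "y", "z")])
  b <- as.matrix(res_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Write a structure to PDB
#'
#' Coordinates are written at 3-decimal PDB precision, so a written file
#' re-parses to an equal structure within 1e-3 Angstrom.
#'
#' @param s A structure tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  s <- as_structure(s)
  if (any(nchar(s$chain_id) > 1)) {
    abort("PDB output requires single-character chain identifiers")
  }
  s <- arrange(s, .data$chain_id, .data$resno, .data$icode)
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
      resno = s$resno, resid = s$resname, chain = s$chain_id,
      insert = ifelse(s$icode == "", "", s$icode),
      elety = s$atom, o = s$occupancy, b = rep(0, nrow(s)),
      elesy = s$element
    )
    TRUE
  }, error = function(e) abort(paste0("could not write ", path, ": ",
                                      conditionMessage(e))))
  invisible(path)
}

#' Check the reference-structure interface distances
#'
#' Optional external check against the deposited spinach plastid ribosome
#' (PDB 5MMM, to be downloaded by the user): verifies that the rps11-rps21
#' interface contains the Pro98-Ile113 contact at 3.47 A and the
#' Lys135-Glu127 salt bridge at 3.12 A, the two distances tabulated for this
#' interface.
#'
#' @param path Path to a locally available coordinate file of the reference
#'   ribosome (or any structure mimicking it).
#' @param chain_map Chain map resolving `rps11` (plastid) and `rps21`
#'   (nuclear); see [read_chain_map()].
#' @param format Coordinate format, as in [read_structure()].
#' @param tol Distance tolerance in Angstrom (default 0.05).
#' @return A tibble with one row per checked contact: expected and observed
#'   distance and a logical `ok`.
#' @export
check_reference_interface <- function(path, chain_map, format = "auto", tol = 0.05) {
  s <- read_structure(path, format = format, chain_map = chain_map)
  s <- select_chains(s, c("rps11", "rps21"))
  cm <- as_chain_map(chain_map)
  ch11 <- cm$chain_id[cm$protein == "rps11"]
  ch21 <- cm$chain_id[cm$protein == "rps21"]
  expected <- tibble(
    resno_a = c(98L, 135L), resno_b = c(113L, 127L),
    contact = c("Pro98-Ile113", "Lys135-Glu127"),
    expected = c(3.47, 3.12)
  )
  expected$observed <- purrr::map2_dbl(expected$resno_a, expected$resno_b, function(a, b) {
    min_residue_distance(residue_atoms(s, ch11, a), residue_atoms(s, ch21, b))
  })
  expected$ok <- abs(expected$observed - expected$expected) <= tol
  expected[, c("contact", "expected", "observed", "ok")]
}
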