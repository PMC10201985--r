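# Idealized side-chain geometry: internal-coordinate templates per amino acid,
# NeRF placement, a coarse backbone-independent rotamer library, and the
# heavy-atom clash score used for rotamer selection and chi-grid relaxation.

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

# Place atom D given positions of A, B, C with bond |D-C|, angle D-C-B and
# torsion A-B-C-D (degrees). Natural extension reference frame construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  d_local <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), -bond * sin(ang) * sin(tor))
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Torsion angle A-B-C-D in degrees, in (-180, 180].
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  deg <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (deg <= -180) deg + 360 else deg
}

# Internal-coordinate template rows: atom, r1, r2, r3 (torsion r1-r2-r3-atom,
# bond atom-r3, angle atom-r3-r2), bond (A), angle (deg), dih (a "chiK"
# (+offset) token or a fixed torsion in degrees). CB is placed off the
# backbone with a fixed improper torsion; ring/terminal branches hang off the
# chi chain with fixed offsets. Bond lengths and angles are standard
# idealized values; chemistry realism beyond contact geometry is not a goal.
sidechain_row <- function(atom, r1, r2, r3, bond, angle, dih) {
  tibble(atom = atom, r1 = r1, r2 = r2, r3 = r3,
         bond = bond, angle = angle, dih = dih)
}

cb_row <- function() sidechain_row("CB", "C", "N", "CA", 1.530, 110.5, "122.6")
g_ref <- c("N", "CA", "CB")

sidechain_templates <- local({
  t <- list()
  t$GLY <- sidechain_row(character(0), character(0), character(0), character(0),
                         numeric(0), numeric(0), character(0))
  t$ALA <- cb_row()
  t$SER <- bind_rows(cb_row(), sidechain_row("OG", g_ref[1], g_ref[2], g_ref[3], 1.417, 110.8, "chi1"))
  t$CYS <- bind_rows(cb_row(), sidechain_row("SG", g_ref[1], g_ref[2], g_ref[3], 1.808, 113.8, "chi1"))
  t$THR <- bind_rows(
    cb_row(),
    sidechain_row("OG1", "N", "CA", "CB", 1.433, 109.6, "chi1"),
    sidechain_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120")
  )
  t$VAL <- bind_rows(
    cb_row(),
    sidechain_row("CG1", "N", "CA", "CB", 1.527, 110.5, "chi1"),
    sidechain_row("CG2", "N", "CA", "CB", 1.527, 110.5, "chi1+122")
  )
  t$LEU <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.530, 116.3, "chi1"),
    sidechain_row("CD1", "CA", "CB", "CG", 1.524, 110.7, "chi2"),
    sidechain_row("CD2", "CA", "CB", "CG", 1.525, 110.7, "chi2+122")
  )
  t$ILE <- bind_rows(
    cb_row(),
    sidechain_row("CG1", "N", "CA", "CB", 1.530, 110.4, "chi1"),
    sidechain_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-122"),
    sidechain_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, "chi2")
  )
  t$MET <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
    sidechain_row("SD", "CA", "CB", "CG", 1.803, 112.7, "chi2"),
    sidechain_row("CE", "CB", "CG", "SD", 1.791, 100.9, "chi3")
  )
  t$PRO <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.495, 104.5, "chi1"),
    sidechain_row("CD", "CA", "CB", "CG", 1.507, 105.5, "chi2")
  )
  phe_core <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
    sidechain_row("CD1", "CA", "CB", "CG", 1.384, 120.8, "chi2"),
    sidechain_row("CD2", "CA", "CB", "CG", 1.384, 120.8, "chi2+180"),
    sidechain_row("CE1", "CB", "CG", "CD1", 1.382, 121.0, "180"),
    sidechain_row("CE2", "CB", "CG", "CD2", 1.382, 121.0, "180"),
    sidechain_row("CZ", "CG", "CD1", "CE1", 1.382, 120.0, "0")
  )
  t$PHE <- phe_core
  t$TYR <- bind_rows(phe_core, sidechain_row("OH", "CD1", "CE1", "CZ", 1.376, 119.9, "180"))
  t$TRP <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.498, 113.6, "chi1"),
    sidechain_row("CD1", "CA", "CB", "CG", 1.365, 126.9, "chi2"),
    sidechain_row("CD2", "CA", "CB", "CG", 1.433, 126.7, "chi2+180"),
    sidechain_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, "180"),
    sidechain_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, "180"),
    sidechain_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, "0"),
    sidechain_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, "180"),
    sidechain_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, "180"),
    sidechain_row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, "0")
  )
  t$ASP <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
    sidechain_row("OD1", "CA", "CB", "CG", 1.249, 118.4, "chi2"),
    sidechain_row("OD2", "CA", "CB", "CG", 1.249, 118.4, "chi2+180")
  )
  t$ASN <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
    sidechain_row("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
    sidechain_row("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2+180")
  )
  t$GLU <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
    sidechain_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
    sidechain_row("OE1", "CB", "CG", "CD", 1.249, 118.4, "chi3"),
    sidechain_row("OE2", "CB", "CG", "CD", 1.249, 118.4, "chi3+180")
  )
  t$GLN <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
    sidechain_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
    sidechain_row("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
    sidechain_row("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3+180")
  )
  t$LYS <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
    sidechain_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
    sidechain_row("CE", "CB", "CG", "CD", 1.520, 111.3, "chi3"),
    sidechain_row("NZ", "CG", "CD", "CE", 1.489, 111.9, "chi4")
  )
  t$ARG <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
    sidechain_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
    sidechain_row("NE", "CB", "CG", "CD", 1.461, 112.0, "chi3"),
    sidechain_row("CZ", "CG", "CD", "NE", 1.330, 124.2, "chi4"),
    sidechain_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, "0"),
    sidechain_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, "180")
  )
  t$HIS <- bind_rows(
    cb_row(),
    sidechain_row("CG", "N", "CA", "CB", 1.497, 113.8, "chi1"),
    sidechain_row("ND1", "CA", "CB", "CG", 1.371, 122.7, "chi2"),
    sidechain_row("CD2", "CA", "CB", "CG", 1.356, 131.0, "chi2+180"),
    sidechain_row("CE1", "CB", "CG", "ND1", 1.319, 109.0, "180"),
    sidechain_row("NE2", "CB", "CG", "CD2", 1.374, 107.0, "180")
  )
  t
})

#' Canonical heavy-atom side-chain inventory
#'
#' @param aa3 Three-letter residue name (standard amino acid).
#' @return Character vector of side-chain heavy-atom names (empty for GLY).
#' @export
canonical_side_chain_atoms <- function(aa3) {
  aa3 <- toupper(aa3)
  if (!aa3 %in% names(sidechain_templates)) {
    abort(paste0("unsupported residue type: ", aa3))
  }
  sidechain_templates[[aa3]]$atom
}

n_chi <- function(aa3) {
  dih <- sidechain_templates[[toupper(aa3)]]$dih
  hits <- regmatches(dih, regexpr("^chi[0-9]", dih))
  if (length(hits) == 0) return(0L)
  max(as.integer(sub("chi", "", hits)))
}

# Which chi angles rotate an sp2/terminal planar group (carboxylate, amide,
# aromatic ring, guanidinium) rather than an sp3 bond.
sp2_chi <- list(
  ASP = 2L, ASN = 2L, PHE = 2L, TYR = 2L, TRP = 2L, HIS = 2L,
  GLU = 3L, GLN = 3L, ARG = 4L
)

#' Coarse rotamer candidate set
#'
#' A small built-in backbone-independent library: canonical chi combinations
#' (gauche-/gauche+/trans for sp3 torsions, planar-group orientations for
#' terminal sp2 torsions, puckered values for proline) with multiplicative
#' priors.
#'
#' @param aa3 Three-letter residue name.
#' @return A tibble with one row per candidate: columns `chi1`..`chik` and
#'   `prior`. Residues without rotatable chi angles get a single candidate
#'   with no chi columns.
#' @export
rotamer_candidates <- function(aa3) {
  aa3 <- toupper(aa3)
  k <- n_chi(aa3)
  if (k == 0) return(tibble(prior = 1))
  sets <- vector("list", k)
  priors <- vector("list", k)
  for (i in seq_len(k)) {
    if (aa3 == "PRO") {
      sets[[i]] <- if (i == 1) c(-25, 25) else c(-35, 35)
      priors[[i]] <- c(0.5, 0.5)
    } else if (!is.null(sp2_chi[[aa3]]) && i == sp2_chi[[aa3]]) {
      sets[[i]] <- c(-90, 0, 90)
      priors[[i]] <- c(0.35, 0.25, 0.40)
    } else {
      sets[[i]] <- c(-60, 60, 180)
      priors[[i]] <- c(0.35, 0.20, 0.45)
    }
  }
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(k)), drop = FALSE]
  names(grid) <- paste0("chi", seq_len(k))
  pgrid <- expand.grid(rev(priors), KEEP.OUT.ATTRS = FALSE)
  prior <- apply(pgrid, 1, prod)
  out <- as_tibble(grid)
  out$prior <- prior
  out
}

# Build side-chain atoms for aa3 on the given backbone (named 3-vectors N,
# CA, C) at the given chi angles. Returns a tibble atom/element/x/y/z.
build_side_chain <- function(aa3, backbone, chis = numeric(0)) {
  aa3 <- toupper(aa3)
  tmpl <- sidechain_templates[[aa3]]
  if (is.null(tmpl)) abort(paste0("unsupported residue type: ", aa3))
  if (nrow(tmpl) == 0) {
    return(tibble(atom = character(0), element = character(0),
                  x = numeric(0), y = numeric(0), z = numeric(0)))
  }
  if (length(chis) < n_chi(aa3)) {
    abort(paste0(aa3, " needs ", n_chi(aa3), " chi angle(s)"))
  }
  coords <- list(N = backbone$N, CA = backbone$CA, C = backbone$C)
  for (i in seq_len(nrow(tmpl))) {
    row <- tmpl[i, ]
    dih <- resolve_dihedral(row$dih, chis)
    coords[[row$atom]] <- place_atom(coords[[row$r1]], coords[[row$r2]],
                                     coords[[row$r3]], row$bond, row$angle, dih)
  }
  placed <- coords[tmpl$atom]
  tibble(
    atom = tmpl$atom,
    element = derive_element(tmpl$atom),
    x = unname(purrr::map_dbl(placed, 1)),
    y = unname(purrr::map_dbl(placed, 2)),
    z = unname(purrr::map_dbl(placed, 3))
  )
}

resolve_dihedral <- function(spec, chis) {
  m <- regmatches(spec, regexec("^chi([0-9])([+-][0-9.]+)?$", spec))[[1]]
  if (length(m) > 0) {
    val <- chis[as.integer(m[2])]
    if (m[3] != "") val <- val + as.numeric(m[3])
    ((val + 180) %% 360) - 180
  } else {
    as.numeric(spec)
  }
}

# The (r1, r2, r3, atom) quadruples defining each chi torsion, for measuring
# chi angles off built coordinates.
chi_quadruples <- function(aa3) {
  tmpl <- sidechain_templates[[toupper(aa3)]]
  rows <- tmpl[grepl("^chi[0-9]$", tmpl$dih), ]
  rows[order(rows$dih), c("r1", "r2", "r3", "atom")]
}

measure_chis <- function(res) {
  aa3 <- res$resname[1]
  quads <- chi_quadruples(aa3)
  if (nrow(quads) == 0) return(numeric(0))
  coord <- function(name) {
    row <- res[res$atom == name, ]
    if (nrow(row) == 0) abort(paste0("atom ", name, " missing from residue"))
    c(row$x[1], row$y[1], row$z[1])
  }
  purrr::pmap_dbl(quads, function(r1, r2, r3, atom) {
    torsion_angle(coord(r1), coord(r2), coord(r3), coord(atom))
  })
}

#' Heavy-atom clash score of a side chain against its surroundings
#'
#' Counts non-bonded heavy-atom pairs closer than `threshold` between the
#' side-chain atoms of one residue and all atoms of every other residue. The
#' residue's own backbone (and intra-residue pairs, which are bonded or 1-3)
#' is excluded.
#'
#' @param s A structure tibble.
#' @param chain,number,icode Identify the residue whose side chain is scored.
#' @param threshold Clash distance in Angstrom (default 2.5, the lower edge
#'   of the interaction window).
#' @return Integer clash count.
#' @export
clash_score <- function(s, chain, number, icode = "", threshold = 2.5) {
  own <- s$chain_id == chain & s$resno == number & s$icode == icode
  side <- own & !(s$atom %in% c("N", "CA", "C", "O", "OXT"))
  if (!any(side)) return(0L)
  rest <- as.matrix(s[!own, c("x", "y", "z")])
  if (nrow(rest) == 0) return(0L)
  sc <- as.matrix(s[side, c("x", "y", "z")])
  d2 <- outer(rowSums(sc^2), rowSums(rest^2), "+") - 2 * tcrossprod(sc, rest)
  sum(d2 < threshold^2)
}
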