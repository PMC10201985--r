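test_that("substitution rebuilds the canonical atom inventory", {
  toy <- make_toy_dimer(6)
  s <- toy$structure
  for (aa1 in c("S", "K", "W", "P", "V")) {
    mut <- substitute_residue(s, "A", 2, aa1)
    res <- residue_atoms(mut, "A", 2)
    aa3 <- c(S = "SER", K = "LYS", W = "TRP", P = "PRO", V = "VAL")[[aa1]]
    expect_identical(unique(res$resname), aa3)
    expect_setequal(res$atom, c("N", "CA", "C", "O", canonical_side_chain_atoms(aa3)))
  }
  # a proline-to-serine change gives exactly the serine atom set
  mut <- substitute_residue(substitute_residue(s, "A", 3, "P"), "A", 3, "S")
  expect_setequal(residue_atoms(mut, "A", 3)$atom,
                  c("N", "CA", "C", "O", "CB", "OG"))
})

test_that("glycine targets remove the side chain and keep the backbone bit-identical", {
  toy <- make_toy_dimer(5)
  ala <- substitute_residue(toy$structure, "A", 2, "A")
  expect_true("CB" %in% residue_atoms(ala, "A", 2)$atom)
  gly <- substitute_residue(ala, "A", 2, "G")
  res <- residue_atoms(gly, "A", 2)
  expect_setequal(res$atom, c("N", "CA", "C", "O"))
  before <- dplyr::arrange(
    dplyr::filter(ala, atom %in% c("N", "CA", "C", "O")), chain_id, resno, atom)
  after <- dplyr::arrange(
    dplyr::filter(gly, atom %in% c("N", "CA", "C", "O")), chain_id, resno, atom)
  expect_identical(before[, c("x", "y", "z")], after[, c("x", "y", "z")])
})

test_that("substituting a non-existent or non-standard residue errors", {
  toy <- make_toy_dimer(4)
  expect_error(substitute_residue(toy$structure, "A", 99, "S"), "not found")
  odd <- toy$structure
  odd$resname[odd$chain_id == "A" & odd$resno == 1] <- "MSE"
  odd$standard[odd$chain_id == "A" & odd$resno == 1] <- FALSE
  expect_error(substitute_residue(odd, "A", 1, "S"), "non-standard")
})

test_that("rotamer choice minimizes the clash count deterministically", {
  toy <- make_toy_dimer(6)
  s <- toy$structure
  # empty surroundings: the highest-prior candidate (all-trans) is returned
  chis <- choose_rotamer(s, "A", 3, "LYS")
  expect_identical(unname(as.numeric(chis)), c(180, 180, 180, 180))
  expect_identical(attr(chis, "clash"), 0L)
  # engineered pocket: block two of the three serine chi1 wells (with atoms
  # placed radially beyond the OG position, clear of the fixed CB) so exactly
  # one candidate is clash-free
  bb <- cybrin:::residue_backbone(residue_atoms(s, "A", 3))
  cb <- build_side_chain("SER", bb, 0)
  cb <- as.numeric(cb[cb$atom == "CB", c("x", "y", "z")])
  blockers <- dplyr::bind_rows(lapply(c(180, -60), function(chi) {
    og <- build_side_chain("SER", bb, chi)
    og <- as.numeric(og[og$atom == "OG", c("x", "y", "z")])
    pos <- og + 1.2 * (og - cb) / sqrt(sum((og - cb)^2))
    tibble::tibble(chain_id = "B", protein = "ntoy", compartment = "nuclear",
                   resno = 90L + as.integer(chi), icode = "", resname = "GLY",
                   atom = "CB", element = "C", x = pos[1], y = pos[2], z = pos[3],
                   occupancy = 1, altloc = "", standard = TRUE)
  }))
  crowded <- as_structure(dplyr::bind_rows(s, blockers))
  picked <- choose_rotamer(crowded, "A", 3, "SER")
  expect_identical(unname(as.numeric(picked)), 60)
  expect_identical(attr(picked, "clash"), 0L)
  # the returned clash is never beaten by any candidate
  cands <- rotamer_candidates("SER")
  scores <- vapply(seq_len(nrow(cands)), function(i) {
    side <- build_side_chain("SER", bb, cands$chi1[i])
    n_clash <- 0L
    for (a in seq_len(nrow(side))) {
      for (b in seq_len(nrow(blockers))) {
        d <- sqrt((side$x[a] - blockers$x[b])^2 + (side$y[a] - blockers$y[b])^2 +
                    (side$z[a] - blockers$z[b])^2)
        if (d < 2.5) n_clash <- n_clash + 1L
      }
    }
    n_clash
  }, integer(1))
  expect_identical(min(scores), attr(picked, "clash"))
})

test_that("chi-grid relaxation resolves engineered clashes and never worsens", {
  toy <- make_toy_dimer(6)
  s <- substitute_residue(toy$structure, "A", 3, "S")
  # clash-free side chain is left untouched
  relaxed <- relax_side_chain(s, "A", 3)
  expect_identical(clash_score(relaxed, "A", 3), clash_score(s, "A", 3))
  # plant a blocker just beyond the current OG: a chi1 rotation resolves it
  res3 <- residue_atoms(s, "A", 3)
  og <- res3[res3$atom == "OG", ]
  cb <- res3[res3$atom == "CB", ]
  dir <- c(og$x - cb$x, og$y - cb$y, og$z - cb$z)
  dir <- dir / sqrt(sum(dir^2))
  blocker <- og
  blocker$x <- og$x + 1.2 * dir[1]
  blocker$y <- og$y + 1.2 * dir[2]
  blocker$z <- og$z + 1.2 * dir[3]
  blocker$chain_id <- "B"; blocker$resno <- 99L
  blocker$protein <- "ntoy"; blocker$compartment <- "nuclear"
  crowded <- as_structure(dplyr::bind_rows(s, blocker))
  expect_gt(clash_score(crowded, "A", 3), 0)
  fixed <- relax_side_chain(crowded, "A", 3)
  expect_identical(clash_score(fixed, "A", 3), 0L)
  # monotonicity across random structures and residue types
  for (seed in 1:6) {
    t2 <- make_toy_dimer(6, random_toy_plan(6, 3, seed), seed = seed)
    s2 <- substitute_residue(t2$structure, "A", 2, c("K", "L", "R", "F", "M", "E")[seed])
    before <- clash_score(s2, "A", 2)
    after <- clash_score(relax_side_chain(s2, "A", 2), "A", 2)
    expect_lte(after, before)
  }
})

test_that("combination enumeration and model building follow the cross design", {
  lineages <- c("E1", "W1", "W2", "W3")
  ids <- combination_ids(lineages)
  expect_identical(nrow(ids), 16L)
  expect_identical(ids$label[1], "E1_E1")
  expect_identical(ids$label[16], "W3_W3")
  expect_identical(nrow(combination_ids(c("a", "b"))), 4L)

  toy <- make_toy_dimer(6)
  subs <- tibble::tibble(
    lineage = c("E1", "W1", "W1"),
    gene = c("ptoy", "ptoy", "ntoy"),
    ref_number = c(2L, 2L, 4L),
    new_aa = c("K", "S", "L")
  )
  # E1_W1: plastid changes from E1, nuclear changes from W1 only
  m <- build_combination_model(toy$structure, "E1", "W1", subs, toy$chain_map)
  expect_identical(unique(residue_atoms(m$structure, "A", 2)$resname), "LYS")
  expect_identical(unique(residue_atoms(m$structure, "B", 4)$resname), "LEU")
  # W1_E1 reverses the roles: plastid gets W1's serine, nuclear untouched
  m2 <- build_combination_model(toy$structure, "W1", "E1", subs, toy$chain_map)
  expect_identical(unique(residue_atoms(m2$structure, "A", 2)$resname), "SER")
  expect_identical(unique(residue_atoms(m2$structure, "B", 4)$resname), "GLY")
  # a combination with no substitutions reproduces the template exactly
  m3 <- build_combination_model(toy$structure, "W2", "W2", subs, toy$chain_map)
  expect_identical(m3$structure, as_structure(toy$structure))
  # unknown gene in the substitution table is a configuration error
  bad <- dplyr::mutate(subs, gene = "ghost")
  expect_error(build_combination_model(toy$structure, "E1", "W1", bad,
                                       toy$chain_map), "chain map")
  # missing residues are reported unapplied
  far <- dplyr::mutate(subs, ref_number = 999L)
  m4 <- build_combination_model(toy$structure, "E1", "W1", far, toy$chain_map)
  expect_true(all(!m4$applied$applied))
})

test_that("backbone coordinates are exactly preserved in combination models", {
  toy <- make_toy_dimer(6, random_toy_plan(6, 3, 2), seed = 2)
  subs <- tibble::tibble(lineage = "E1", gene = c("ptoy", "ntoy"),
                         ref_number = c(2L, 3L), new_aa = c("R", "F"))
  m <- build_combination_model(toy$structure, "E1", "E1", subs, toy$chain_map)
  bb <- function(s) dplyr::arrange(
    dplyr::filter(s, atom %in% c("N", "CA", "C", "O")), chain_id, resno, atom)
  expect_identical(bb(m$structure)[, c("x", "y", "z")],
                   bb(toy$structure)[, c("x", "y", "z")])
})

test_that("applying a substitution set twice equals applying it once", {
  toy <- make_toy_dimer(6, random_toy_plan(6, 2, 7), seed = 7)
  targets <- tibble::tibble(chain_id = c("A", "A", "B"), resno = c(2L, 3L, 4L),
                            new_aa = c("K", "F", "E"))
  once <- substitute_residues(toy$structure, targets, relax = TRUE)
  twice <- substitute_residues(once, targets, relax = TRUE)
  expect_equal(dplyr::arrange(twice, chain_id, resno, atom),
               dplyr::arrange(once, chain_id, resno, atom), tolerance = 1e-12)
})
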