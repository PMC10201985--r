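test_that("minimal residue distance is symmetric, non-negative and analytic", {
  toy <- make_toy_dimer(5, tibble::tibble(res_a = 2, res_b = 3, distance = 4.0))
  s <- toy$structure
  a <- residue_atoms(s, "A", 2)
  b <- residue_atoms(s, "B", 3)
  expect_equal(min_residue_distance(a, b), 4.0, tolerance = 1e-9)
  expect_identical(min_residue_distance(a, b), min_residue_distance(b, a))
  expect_identical(min_residue_distance(a, a), 0)
  one_atom <- function(x, y, z) {
    tibble::tibble(atom = "X", element = "C", x = x, y = y, z = z)
  }
  expect_equal(min_residue_distance(one_atom(0, 0, 0), one_atom(0, 0, 4)), 4)
  # random pairs: symmetry and zero iff shared atom position
  for (seed in 1:10) {
    t2 <- make_toy_dimer(6, random_toy_plan(6, 4, seed), seed = seed)
    ra <- residue_atoms(t2$structure, "A", 1)
    rb <- residue_atoms(t2$structure, "B", 6)
    expect_identical(min_residue_distance(ra, rb), min_residue_distance(rb, ra))
    expect_gte(min_residue_distance(ra, rb), 0)
  }
})

test_that("PDB write/parse is a fixed point on synthetic structures", {
  toy <- make_toy_dimer(6, random_toy_plan(6, 4, seed = 11), seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$structure, path)
  back <- read_structure(path, format = "pdb", chain_map = toy$chain_map)
  orig <- dplyr::arrange(toy$structure, chain_id, resno, atom)
  got <- dplyr::arrange(back, chain_id, resno, atom)
  expect_identical(got[, c("chain_id", "resno", "resname", "atom")],
                   orig[, c("chain_id", "resno", "resname", "atom")])
  expect_lt(max(abs(got$x - orig$x), abs(got$y - orig$y), abs(got$z - orig$z)),
            1e-3)
  # second round trip is exact (coordinates already at PDB precision)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(back, path2)
  back2 <- read_structure(path2, format = "pdb", chain_map = toy$chain_map)
  expect_identical(dplyr::arrange(back2, chain_id, resno, atom)$x, got$x)
})

test_that("mutant model round trip preserves the substituted residue", {
  toy <- make_toy_dimer(5)
  mut <- substitute_residue(toy$structure, "A", 3, "W")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(mut, path)
  back <- read_structure(path, chain_map = toy$chain_map)
  res <- residue_atoms(back, "A", 3)
  expect_identical(unique(res$resname), "TRP")
  expect_setequal(res$atom, c("N", "CA", "C", "O", canonical_side_chain_atoms("TRP")))
})

test_that("alternate locations keep the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   SER A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   SER A   1       3.200   1.500   0.000  1.00  0.00           O",
    "ATOM      5  CB ASER A   1       1.900  -0.800   1.200  0.40  0.00           C",
    "ATOM      6  CB BSER A   1       1.950  -0.850   1.250  0.60  0.00           C",
    "ATOM      7  OG ASER A   1       1.500  -2.100   1.200  0.50  0.00           O",
    "ATOM      8  OG BSER A   1       1.550  -2.150   1.250  0.50  0.00           O",
    "END"
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- read_structure(path)
  cb <- s[s$atom == "CB", ]
  og <- s[s$atom == "OG", ]
  expect_identical(nrow(cb), 1L)
  expect_identical(cb$altloc, "B") # higher occupancy wins
  expect_identical(og$altloc, "A") # occupancy tie broken by letter order
})

test_that("waters are excluded and a single residue parses whole", {
  lines <- c(
    "ATOM      1  N   GLY A   7       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   7       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   7       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   7       3.200   1.500   0.000  1.00  0.00           O",
    "HETATM    5  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
    "END"
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- read_structure(path)
  expect_identical(nrow(s), 4L)
  expect_identical(unique(s$chain_id), "A")
  expect_identical(unique(s$resno), 7L)
})

test_that("chain annotation and selection behave per the chain map", {
  toy <- make_toy_dimer(4)
  s <- toy$structure
  expect_setequal(unique(s$compartment), c("plastid", "nuclear"))
  only_a <- select_chains(s, "ptoy")
  expect_identical(unique(only_a$chain_id), "A")
  # identity and idempotence
  both <- select_chains(s, c("ptoy", "ntoy"))
  expect_identical(both, s)
  expect_identical(select_chains(both, c("ptoy", "ntoy")), both)
  expect_error(select_chains(s, "rps11"), "unknown protein")
  # chain map naming an absent chain is a configuration error
  bad_map <- tibble::tibble(protein = "ghost", chain_id = "Z",
                            compartment = "plastid", offset = 0L)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  expect_error(read_structure(path, chain_map = bad_map), "absent from the file")
  expect_error(read_structure("no_such_file.pdb"), "not found")
})

test_that("chain maps load from YAML and JSON with offsets", {
  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rps11: {chain: \"A\", compartment: plastid}",
               "rps21: {chain: \"B\", compartment: nuclear, offset: 2}"), ypath)
  cm <- read_chain_map(ypath)
  expect_identical(cm$offset, c(0L, 2L))
  expect_identical(cm$compartment, c("plastid", "nuclear"))
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(rps11 = list(chain = "A", compartment = "plastid")),
    jpath, auto_unbox = TRUE
  )
  expect_identical(read_chain_map(jpath)$chain_id, "A")
  expect_error(read_chain_map(list(g = list(chain = "A", compartment = "weird"))),
               "compartment")
})

test_that("the reference-interface check accepts a structure with the printed contacts", {
  # synthetic stand-in for the deposited ribosome: plants the two tabulated
  # rps11-rps21 interface distances at their printed values
  toy <- make_toy_dimer(140, tibble::tibble(res_a = c(98, 135),
                                            res_b = c(113, 127),
                                            distance = c(3.47, 3.12)))
  cm <- tibble::tibble(protein = c("rps11", "rps21"), chain_id = c("A", "B"),
                       compartment = c("plastid", "nuclear"), offset = 0L)
  s <- cybrin:::annotate_chains(toy$structure, cm)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  res <- check_reference_interface(path, cm)
  expect_true(all(res$ok))
  expect_equal(res$observed, c(3.47, 3.12), tolerance = 1e-3)
})
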