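mk_res <- function(resname, atoms, xyz) {
  tibble::tibble(
    chain_id = "X", protein = NA_character_, compartment = "other",
    resno = 1L, icode = "", resname = resname,
    atom = atoms, element = cybrin:::derive_element(atoms),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, altloc = "", standard = TRUE
  )
}

test_that("salt bridges outrank hydrogen bonds at charged-carboxylate contacts", {
  # lysine ammonium nitrogen 3.12 A from a glutamate carboxylate oxygen,
  # the tabulated Lys135-Glu127 geometry
  lys <- mk_res("LYS", c("CA", "CE", "NZ"),
                rbind(c(-6, 0, 0), c(-1.5, 0, 0), c(0, 0, 0)))
  glu <- mk_res("GLU", c("CA", "CD", "OE1"),
                rbind(c(9, 0, 0), c(4.3, 0, 0), c(3.12, 0, 0)))
  expect_identical(classify_interaction(lys, glu), "salt_bridge")
  expect_identical(classify_interaction(glu, lys), "salt_bridge")
  # constructed Lys NZ / Asp OD1 at 3.0 A
  asp <- mk_res("ASP", c("CA", "CG", "OD1"),
                rbind(c(9, 0, 0), c(4.2, 0, 0), c(3.0, 0, 0)))
  expect_identical(classify_interaction(lys, asp), "salt_bridge")
  # beyond the 4.0 A salt-bridge cut the same pair drops to polar
  far <- mk_res("GLU", c("CA", "CD", "OE1"),
                rbind(c(10, 0, 0), c(5.5, 0, 0), c(4.4, 0, 0)))
  expect_identical(classify_interaction(lys, far), "polar")
})

test_that("hydrogen bonds, hydrophobic and polar contacts follow the rule order", {
  ser <- mk_res("SER", c("CB", "OG"), rbind(c(-1.4, 0, 0), c(0, 0, 0)))
  thr <- mk_res("THR", c("CB", "OG1"), rbind(c(4.6, 0, 0), c(3.2, 0, 0)))
  expect_identical(classify_interaction(ser, thr), "h_bond")
  leu1 <- mk_res("LEU", c("CB", "CD1"), rbind(c(-1.5, 0, 0), c(0, 0, 0)))
  leu2 <- mk_res("LEU", c("CB", "CD1"), rbind(c(5.5, 0, 0), c(4.0, 0, 0)))
  expect_identical(classify_interaction(leu1, leu2), "hydrophobic")
  # an N/O within the window but outside h-bond range is polar
  ala <- mk_res("ALA", "CB", rbind(c(4.0, 0, 0)))
  ser2 <- mk_res("SER", c("CB", "OG"), rbind(c(-1.4, 0, 0), c(0, 0, 0)))
  expect_identical(classify_interaction(ser2, ala), "polar")
  # two alanines 7 A apart interact with nothing
  ala1 <- mk_res("ALA", "CB", rbind(c(0, 0, 0)))
  ala2 <- mk_res("ALA", "CB", rbind(c(7, 0, 0)))
  expect_identical(classify_interaction(ala1, ala2), "none")
})

test_that("classification is symmetric across constructed pairs", {
  pool <- list(
    mk_res("LYS", c("CE", "NZ"), rbind(c(-1.5, 0, 0), c(0, 0, 0))),
    mk_res("GLU", c("CD", "OE1"), rbind(c(4.3, 0.5, 0), c(3.1, 0.5, 0))),
    mk_res("LEU", c("CB", "CD1"), rbind(c(5.2, 0, 0), c(3.9, 0, 0))),
    mk_res("SER", c("CB", "OG"), rbind(c(0.8, 3.1, 0), c(0.2, 3.1, 0))),
    mk_res("ALA", "CB", rbind(c(2.2, -2.2, 0)))
  )
  for (i in seq_along(pool)) {
    for (j in seq_along(pool)) {
      if (i == j) next
      expect_identical(classify_interaction(pool[[i]], pool[[j]]),
                       classify_interaction(pool[[j]], pool[[i]]))
    }
  }
})

test_that("typed interface edges come from residue geometry", {
  toy <- make_toy_dimer(4, tibble::tibble(res_a = 1, res_b = 2, distance = 3.4))
  g <- build_rin(toy$structure)
  typed <- type_interface(toy$structure, interface_edges(g, "ptoy", "ntoy"))
  # planted pseudo side-chain carbons on glycine: carbon contact, but GLY is
  # not an apolar type and has no apolar side-chain carbons -> none
  expect_identical(typed$type, "none")
})

test_that("model comparison categorizes losses, gains and type changes", {
  wt <- tibble::tibble(node_a = c("A:1", "A:2", "A:3"),
                       node_b = c("B:1", "B:2", "B:3"),
                       type = c("h_bond", "polar", "hydrophobic"))
  mut <- tibble::tibble(node_a = c("A:2", "A:3", "A:4"),
                        node_b = c("B:2", "B:3", "B:4"),
                        type = c("polar", "salt_bridge", "hydrophobic"))
  rec <- compare_models(wt, mut)
  got <- setNames(rec$category, paste(rec$node_a, rec$node_b))
  expect_identical(got[["A:1 B:1"]], "loss")
  expect_identical(got[["A:2 B:2"]], "unchanged")
  expect_identical(got[["A:3 B:3"]], "type_change")
  expect_identical(got[["A:4 B:4"]], "gain")
  dup <- dplyr::bind_rows(wt, wt[1, ])
  expect_error(compare_models(dup, mut), "duplicate")
})

test_that("random planted contact maps match hand categorization", {
  types <- c("h_bond", "salt_bridge", "hydrophobic", "polar", "none")
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- sample(3:8, 1)
      keys <- paste0("A:", seq_len(n))
      before <- sample(types, n, replace = TRUE)
      after <- sample(types, n, replace = TRUE)
      wt <- tibble::tibble(node_a = keys, node_b = paste0("B:", seq_len(n)),
                           type = before)[before != "none", ]
      mut <- tibble::tibble(node_a = keys, node_b = paste0("B:", seq_len(n)),
                            type = after)[after != "none", ]
      rec <- compare_models(wt, mut)
      for (i in seq_len(n)) {
        if (before[i] == "none" && after[i] == "none") next
        expected <- if (before[i] == after[i]) "unchanged"
        else if (after[i] == "none") "loss"
        else if (before[i] == "none") "gain"
        else "type_change"
        row <- rec[rec$node_a == keys[i], ]
        expect_identical(row$category, expected)
      }
    })
  }
})

test_that("the published record fixture tallies to the reported counts", {
  t1 <- table1_fixture()
  counts <- categorize_changes(t1)
  expect_identical(counts$loss, 8L)
  expect_identical(counts$gain, 4L)
  expect_identical(counts$unchanged, 16L)
  expect_identical(counts$type_change, 0L)
  expect_identical(counts$total, 28L)
  expect_identical(counts$loss + counts$gain + counts$type_change +
                     counts$unchanged, counts$total)
  losses <- subtype_tally(t1, "loss")
  expect_identical(losses$n[losses$type == "h_bond"], 4L)
  expect_identical(losses$n[losses$type == "polar"], 2L)
  expect_identical(losses$n[losses$type == "hydrophobic"], 1L)
  expect_identical(losses$n[losses$type == "salt_bridge"], 1L)
  gains <- subtype_tally(t1, "gain")
  expect_identical(gains$n[gains$type == "hydrophobic"], 2L)
  expect_identical(gains$n[gains$type == "polar"], 1L)
  expect_identical(gains$n[gains$type == "h_bond"], 1L)
  # empty input gives all-zero tallies
  empty <- categorize_changes(t1[0, ])
  expect_identical(unlist(empty), c(loss = 0L, gain = 0L, type_change = 0L,
                                    unchanged = 0L, total = 0L))
})

test_that("category invariants hold on every fixture row", {
  t1 <- table1_fixture()
  for (i in seq_len(nrow(t1))) {
    before <- t1$type_before[i]
    variants <- strsplit(t1$type_after[i], "/", fixed = TRUE)[[1]]
    cat_i <- t1$category[i]
    if (cat_i == "loss") {
      expect_true(before != "none" && any(variants == "none"))
    } else if (cat_i == "gain") {
      expect_true(before == "none" && any(variants != "none"))
    } else if (cat_i == "unchanged") {
      expect_true(all(variants == before))
    } else {
      expect_true(before != "none" && all(variants != "none") &&
                    any(variants != before))
    }
  }
})
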