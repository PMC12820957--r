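test_that("consensus merge intersects interaction keys per ligand", {
  a <- make_records("lig1", "Glide",
                    c("hydrogen_bond@271@GLU@V", "hydrophobic_interaction@274@PHE@V"))
  b <- make_records("lig1", "GOLD",
                    c("hydrogen_bond@271@GLU@V", "pi_stack@274@PHE@V"))
  cons <- merge_consensus_interactions(a, b)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$interaction_type, "hydrogen_bond")
  expect_equal(cons$residue_number, 271L)

  # identical inputs (different program labels): consensus = the full set
  b2 <- dplyr::mutate(a, program = "GOLD")
  same <- merge_consensus_interactions(a, b2)
  expect_setequal(
    paste(same$interaction_type, same$residue_number, same$residue_type,
          same$chain),
    paste(a$interaction_type, a$residue_number, a$residue_type, a$chain)
  )

  # disjoint binding modes: empty consensus (no shared contact survives)
  dis <- merge_consensus_interactions(
    make_records("lig1", "Glide", "hydrogen_bond@1@ALA@A"),
    make_records("lig1", "GOLD", "hydrogen_bond@2@GLY@A")
  )
  expect_equal(nrow(dis), 0)
  expect_equal(attr(dis, "empty_ligands"), "lig1")

  expect_error(merge_consensus_interactions(a, dplyr::mutate(b, program = "Glide")),
               "distinct placement|program")
})

test_that("ligands seen by only one program get an empty consensus set", {
  a <- make_records("only_a", "Glide", "hydrogen_bond@10@SER@A")
  b <- make_records("only_b", "GOLD", "hydrogen_bond@10@SER@A")
  expect_warning(cons <- merge_consensus_interactions(a, b), "only_a")
  expect_equal(nrow(cons), 0)
  expect_setequal(attr(cons, "ligand_ids"), c("only_a", "only_b"))
})

test_that("consensus size never exceeds either program's set size", {
  for (seed in 1:5) {
    keys <- paste0("hydrogen_bond@", 1:30, "@ALA@A")
    ab <- withr::with_seed(seed, list(
      a = sample(keys, sample(5:20, 1)),
      b = sample(keys, sample(5:20, 1))
    ))
    cons <- suppressWarnings(merge_consensus_interactions(
      make_records("x", "p1", ab$a), make_records("x", "p2", ab$b)
    ))
    expect_lte(nrow(cons), min(length(ab$a), length(ab$b)))
    expect_setequal(
      paste0("hydrogen_bond@", cons$residue_number, "@ALA@A"),
      intersect(ab$a, ab$b)
    )
  }
})

test_that("fingerprint matrix encodes named bits with deterministic order", {
  cons <- merge_consensus_interactions(
    make_records(c("l1", "l1", "l2", "l3"), "p1",
                 c("hydrogen_bond@85@GLY@C", "hydrophobic_interaction@110@PHE@C",
                   "hydrogen_bond@85@GLY@C", "hydrogen_bond@205@SER@s")),
    make_records(c("l1", "l1", "l2", "l3"), "p2",
                 c("hydrogen_bond@85@GLY@C", "hydrophobic_interaction@110@PHE@C",
                   "hydrogen_bond@85@GLY@C", "hydrogen_bond@205@SER@s"))
  )
  fp <- build_fingerprint_matrix(cons)
  bits <- setdiff(names(fp), "ligand_id")
  expect_equal(bits, c("hydrogen_bond@85@GLY@C", "hydrophobic_interaction@110@PHE@C",
                       "hydrogen_bond@205@SER@s"))
  expect_equal(rowSums(fp[-1]), c(2, 1, 1), ignore_attr = TRUE)
  # every bit set for at least one ligand
  expect_true(all(colSums(fp[-1]) >= 1))
  # deterministic across repeated construction
  expect_identical(fp, build_fingerprint_matrix(cons))

  # empty-consensus ligand keeps an all-zero row
  fp2 <- build_fingerprint_matrix(cons, ligand_ids = c("l1", "l2", "l3", "metf"))
  expect_equal(sum(fp2[fp2$ligand_id == "metf", -1]), 0)
  expect_equal(attr(fp2, "empty_ligands"), "metf")
})

test_that("Tanimoto similarity follows set overlap with the empty convention", {
  fp <- tibble::tibble(
    ligand_id = c("a", "b", "c", "empty1", "empty2"),
    b1 = c(1, 0, 1, 0, 0), b2 = c(1, 1, 1, 0, 0), b3 = c(0, 1, 1, 0, 0)
  )
  tt <- tanimoto_matrix(fp)
  expect_equal(tt["a", "b"], 1 / 3)
  expect_equal(tt["a", "c"], 2 / 3)
  expect_equal(tt["a", "a"], 1)
  expect_true(isSymmetric(unname(unclass(tt))))
  expect_true(all(tt >= 0 & tt <= 1))
  # empty fingerprints are similar to nothing, not even themselves
  expect_equal(tt["empty1", "empty2"], 0)
  expect_equal(tt["empty1", "empty1"], 0)
  expect_setequal(attr(tt, "empty_ligands"), c("empty1", "empty2"))

  ident <- tanimoto_matrix(tibble::tibble(ligand_id = c("x", "y"),
                                          b1 = c(1, 1), b2 = c(1, 1)))
  expect_equal(ident["x", "y"], 1)
})

test_that("geometric isomers with disjoint binding modes score Tanimoto 0", {
  cons <- suppressWarnings(merge_consensus_interactions(
    make_records(c("e_fpm", "e_fpm", "z_fpm"), "Glide",
                 c("hydrogen_bond@85@GLY@C", "hydrophobic_interaction@110@PHE@C",
                   "hydrogen_bond@141@TYR@Q")),
    make_records(c("e_fpm", "e_fpm", "z_fpm"), "GOLD",
                 c("hydrogen_bond@85@GLY@C", "hydrophobic_interaction@110@PHE@C",
                   "hydrogen_bond@141@TYR@Q"))
  ))
  tt <- tanimoto_matrix(build_fingerprint_matrix(cons))
  expect_equal(tt["e_fpm", "z_fpm"], 0)
})

test_that("clustering matches the exhaustive agglomeration oracle", {
  sim <- matrix(c(
    1.0, 0.9, 0.2, 0.1,
    0.9, 1.0, 0.3, 0.2,
    0.2, 0.3, 1.0, 0.6,
    0.1, 0.2, 0.6, 1.0
  ), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  for (linkage in c("average", "complete", "single")) {
    hc <- cluster_fingerprints(sim, linkage = linkage)
    got <- as.matrix(stats::cophenetic(hc))[letters[1:4], letters[1:4]]
    want <- oracle_cophenetic(1 - sim, linkage)
    dimnames(want) <- dimnames(sim)
    expect_equal(got, want, tolerance = 1e-12)
  }

  # a random 6-ligand instance per linkage
  for (seed in 1:3) {
    m <- withr::with_seed(seed, {
      bits <- matrix(rbinom(6 * 8, 1, 0.5), 6)
      fp <- tibble::as_tibble(as.data.frame(bits))
      names(fp) <- paste0("hydrogen_bond@", 1:8, "@ALA@A")
      dplyr::bind_cols(tibble::tibble(ligand_id = paste0("l", 1:6)), fp)
    })
    tt <- tanimoto_matrix(m)
    hc <- cluster_fingerprints(tt)
    got <- as.matrix(stats::cophenetic(hc))[paste0("l", 1:6), paste0("l", 1:6)]
    want <- oracle_cophenetic(1 - tt, "average")
    dimnames(want) <- dimnames(tt)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("identical ligands merge first; permutation preserves heights", {
  fp <- tibble::tibble(ligand_id = c("twin1", "twin2", "loner"),
                       b1 = c(1, 1, 0), b2 = c(1, 1, 0), b3 = c(0, 0, 1))
  hc <- cluster_fingerprints(tanimoto_matrix(fp))
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("twin1", "twin2"))

  perm <- fp[c(3, 1, 2), ]
  hc2 <- cluster_fingerprints(tanimoto_matrix(perm))
  expect_equal(sort(hc2$height), sort(hc$height))

  expect_error(cluster_fingerprints(matrix(1, 1, 1)), "at least 2")
})
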