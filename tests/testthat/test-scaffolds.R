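test_that("bm_scaffold strips substituents but keeps multiply-bonded atoms", {
  # toluene: methyl removed
  expect_equal(bm_scaffold("Cc1ccccc1"), canonical_smiles("c1ccccc1"))
  # acetophenone: the whole acetyl group is a substituent (the carbonyl is
  # not attached to a ring or linker atom), so the scaffold is benzene
  expect_equal(bm_scaffold("CC(=O)c1ccccc1"), canonical_smiles("c1ccccc1"))
  # benzophenone: the carbonyl carbon is a linker, so its double-bonded
  # oxygen stays in the scaffold
  expect_equal(bm_scaffold("c1ccccc1C(=O)c1ccccc1"),
               canonical_smiles("O=C(c1ccccc1)c1ccccc1"))
  # ring-attached carbonyl (cyclohexenone-like) stays
  expect_equal(bm_scaffold("CC1CCCC(=O)C1"),
               canonical_smiles("O=C1CCCCC1"))
})

test_that("the testosterone-like steroid yields the 4-ring ketone scaffold", {
  steroid <- "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O"
  sca <- bm_scaffold(steroid)
  expect_equal(sca, canonical_smiles("O=C1CCC2C(=C1)CCC1C2CCC2C1CCC2"))
  # the scaffold keeps the exocyclic carbonyl oxygen: 18 heavy atoms
  expect_equal(nchar(gsub("[^A-Za-z]", "", gsub("Cl|Br", "X", sca))), 18L)
  expect_equal(ring_count(sca), 4L)
})

test_that("bm_scaffold is idempotent", {
  smis <- c("Cc1ccc2ccccc2c1", "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O",
            "OCCc1ccc2c(c1)OCC2", "c1ccccc1C(=O)c1ccncc1")
  sca <- bm_scaffold(smis)
  expect_equal(bm_scaffold(sca), sca)
})

test_that("bm_scaffold errors on ringless or unparseable input", {
  expect_error(bm_scaffold("CCCC"), "without rings")
  expect_error(bm_scaffold("qq(("), "unparseable")
})

test_that("csk_of erases element and bond-order information", {
  expect_equal(csk_of(bm_scaffold("c1ccncc1")), csk_of(bm_scaffold("c1ccccc1")))
  expect_equal(csk_of(bm_scaffold("C1CCOCC1")), csk_of(bm_scaffold("c1ccccc1")))
  # 6-6 fused systems share one CSK regardless of saturation/heteroatoms
  expect_equal(csk_of(bm_scaffold("c1ccc2ccccc2c1")),
               csk_of(bm_scaffold("C1CCc2ncccc2C1")))
  # but a 6-5 system differs
  expect_false(csk_of(bm_scaffold("C1Cc2ccccc2C1")) ==
                 csk_of(bm_scaffold("c1ccc2ccccc2c1")))
})

test_that("csk_of is idempotent", {
  sca <- bm_scaffold(c("c1ccc2ccccc2c1", "O=C1CCC2C(=C1)CCC1C2CCC2C1CCC2"))
  csk <- csk_of(sca)
  expect_equal(csk_of(csk), csk)
})

test_that("ring_count uses the circuit rank", {
  expect_equal(ring_count(c("c1ccccc1", "c1ccc2ccccc2c1", "C1CC2CCC1CC2")),
               c(1L, 2L, 2L))
})

test_that("assign_scaffolds covers every curated compound exactly once", {
  ds <- toy_clean()$agonist
  asg <- assign_scaffolds(ds)
  expect_setequal(asg$cid, ds$cid)
  expect_equal(nrow(asg), nrow(ds))
  expect_false(anyNA(asg$scaffold))
  expect_false(anyNA(asg$csk))
  naph <- asg[asg$cid == "C_PLAIN", ]
  expect_equal(naph$scaffold, canonical_smiles("c1ccc2ccccc2c1"))
  expect_equal(naph$n_rings, 2L)
})

test_that("summarize_scaffolds partitions scaffolds by exclusivity", {
  summ <- summarize_scaffolds(assign_scaffolds(toy_clean()$agonist))
  tot <- length(summ$exclusive_active) + length(summ$exclusive_inactive) +
    length(summ$overlap)
  expect_equal(tot, summ$n_scaffolds)
  expect_equal(summ$n_scaffolds, 3L)
  expect_equal(summ$n_csk, 2L)
  expect_equal(length(summ$exclusive_active), 2L)
  expect_equal(length(summ$overlap), 1L)
  expect_equal(summ$singleton_fraction, 2 / 3)
  expect_equal(sum(summ$per_scaffold$n_compounds), summ$n_compounds)
  expect_equal(sum(summ$ring_histogram$n_scaffolds), summ$n_scaffolds)
  g <- glance(summ)
  expect_equal(g$n_scaffolds, 3L)
  expect_equal(nrow(tidy(summ)), 3L)
})

test_that("scaffold count never exceeds compound count", {
  asg <- assign_scaffolds(run_pipeline(small_lib()$agonist))
  expect_lte(dplyr::n_distinct(asg$scaffold), dplyr::n_distinct(asg$cid))
  expect_lte(dplyr::n_distinct(asg$csk), dplyr::n_distinct(asg$scaffold))
})

test_that("exclusive_potency_profile ranges over aggregated actives only", {
  ds <- toy_clean()$agonist
  asg <- assign_scaffolds(ds)
  summ <- summarize_scaffolds(asg)
  prof <- exclusive_potency_profile(summ, asg, aggregate_potencies(ds))
  expect_equal(nrow(prof), 2L)
  expect_true(all(prof$pic50_min <= prof$pic50_max))
  expect_setequal(round(prof$pic50_min, 2), c(8, 6.25))
  # no exclusively-active scaffolds -> empty profile, silently
  none <- summ
  none$exclusive_active <- character()
  expect_no_warning(empty <- exclusive_potency_profile(none, asg,
                                                       aggregate_potencies(ds)))
  expect_equal(nrow(empty), 0L)
})
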