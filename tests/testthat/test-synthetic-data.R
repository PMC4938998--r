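test_that("simulation_config validates its arguments", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(fraction_active_agonist = -0.1),
               "proportions")
  expect_error(simulation_config(fraction_active_agonist = 0.7,
                                 fraction_active_antagonist = 0.7),
               "at most 1")
  expect_error(simulation_config(n_compounds = 5L, n_dual_active = 10L),
               "planted")
  expect_error(
    simulation_config(substituent_vocabulary = c("C" = 20)), "13")
})

test_that("the template pool is large, parseable and single-system", {
  pool <- moacliff:::template_pool()
  expect_gte(nrow(pool), 50L)
  expect_false(any(duplicated(pool$canonical)))
  expect_false(anyNA(pool$canonical))
  expect_true(all(ring_count(pool$template) == 2L))
  expect_true(all(pool$skeleton_class %in% c("66", "65", "67")))
})

test_that("generate_library is deterministic per seed", {
  a <- generate_library(small_config())
  b <- generate_library(small_config())
  expect_equal(a$agonist, b$agonist)
  expect_equal(a$antagonist, b$antagonist)
  expect_equal(a$truth$compounds, b$truth$compounds)
  c2 <- generate_library(small_config(seed = 8L))
  expect_false(identical(a$agonist, c2$agonist))
})

test_that("all generated structures are valid and clean compounds are unique", {
  lib <- small_lib()
  expect_false(anyNA(canonical_smiles(lib$truth$compounds$smiles)))
  expect_false(any(duplicated(lib$truth$compounds$smiles)))
  expect_false(any(duplicated(lib$truth$compounds$cid)))
})

test_that("curation recovers exactly the clean compounds and injected counts", {
  lib <- small_lib()
  for (arm in c("agonist", "antagonist")) {
    ds <- suppressWarnings(run_pipeline(lib[[arm]]))
    expect_equal(audit_trail(ds)$n_removed, lib$truth$audit_expected$n_removed)
    expect_setequal(ds$smiles, lib$truth$compounds$smiles)
    expect_equal(
      sort(ds$cid[ds$outcome == "Active"]),
      sort(lib$truth$compounds$cid[
        lib$truth$compounds[[paste0(arm, "_outcome")]] == "Active"])
    )
  }
})

test_that("planted labels are consistent with the outcome columns", {
  cmp <- small_lib()$truth$compounds
  expect_true(all(cmp$label_set[cmp$series_kind == "dual"] == "dual"))
  strong <- cmp[cmp$series_kind == "strong", ]
  expect_setequal(strong$label_set, c("agonist", "antagonist"))
  # duals only where planted or via planted weak pairs
  expect_true(all(cmp$series_kind[which(cmp$label_set == "dual")] %in%
                    c("dual", "weak")))
})

test_that("active fractions converge to the configured rates", {
  cfg <- simulation_config(seed = 42L, n_compounds = 500L)
  cmp <- generate_library(cfg)$truth$compounds
  plain <- cmp[cmp$series_kind == "plain", ]
  for (arm in c("agonist", "antagonist")) {
    p <- cfg[[paste0("fraction_active_", arm)]]
    obs <- mean(plain[[paste0(arm, "_outcome")]] == "Active")
    se <- sqrt(p * (1 - p) / nrow(plain))
    expect_lt(abs(obs - p), 4 * se + 1e-12)
  }
})

test_that("potency truth respects the configured pIC50 range", {
  lib <- small_lib()
  pr <- lib$truth$config$potency_range
  expect_true(all(lib$truth$potency$pic50 >= pr[1] &
                    lib$truth$potency$pic50 <= pr[2]))
})

test_that("the analytic MMP truth lists every within-series pair once", {
  truth <- small_lib()$truth
  sizes <- table(truth$compounds$series_id)
  expect_equal(nrow(truth$mmp_pairs), sum(choose(sizes, 2)))
  k <- pair_key(truth$mmp_pairs$cid_left, truth$mmp_pairs$cid_right)
  expect_false(any(duplicated(k)))
})

test_that("the toy fixture carries one artifact per curation stage", {
  t <- toy_assay_fixture()
  trail <- audit_trail(run_pipeline(t$agonist))
  expect_equal(trail$n_removed[trail$stage != "collapse_redundant"],
               rep(1L, 5L))
  expect_equal(nrow(run_pipeline(t$agonist)), t$truth$n_clean)
})
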