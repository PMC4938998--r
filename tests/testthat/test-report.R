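test_that("run_all writes every contracted output with checksums", {
  lib <- small_lib()
  out <- withr::local_tempdir()
  man <- suppressWarnings(
    run_all(lib$agonist, lib$antagonist, out_dir = out, seed = 1)
  )
  expected <- c(
    "audit_agonist.csv", "audit_antagonist.csv",
    "clean_agonist.csv", "clean_antagonist.csv",
    "scaffolds_agonist.csv", "scaffolds_antagonist.csv",
    "fig1_hist_agonist.csv", "fig1_hist_antagonist.csv",
    "exclusive_scaffolds_agonist.csv", "exclusive_scaffolds_antagonist.csv",
    "mmps_agonist.csv", "mmps_antagonist.csv",
    "network_agonist.graphml", "network_agonist.sif",
    "network_antagonist.graphml", "network_antagonist.sif",
    "table1.csv", "table2.csv", "moa_profiles.csv", "dual_action.csv",
    "moa_pairs.csv", "table3.csv"
  )
  expect_setequal(names(man$files), expected)
  for (f in man$files) {
    expect_true(file.exists(f$path))
    expect_equal(unname(tools::md5sum(f$path)), f$md5)
  }
  expect_true(file.exists(file.path(out, "manifest.json")))
})

test_that("re-running with the same config reproduces identical tables", {
  lib <- small_lib()
  o1 <- withr::local_tempdir()
  o2 <- withr::local_tempdir()
  m1 <- suppressWarnings(run_all(lib$agonist, lib$antagonist, o1, seed = 1,
                                 with_diversity = FALSE))
  m2 <- suppressWarnings(run_all(lib$agonist, lib$antagonist, o2, seed = 1,
                                 with_diversity = FALSE))
  for (nm in names(m1$files)) {
    expect_equal(m1$files[[nm]]$md5, m2$files[[nm]]$md5, label = nm)
  }
})

test_that("table 1 obeys the partition and pigeonhole identities", {
  lib <- small_lib()
  ds <- list(agonist = suppressWarnings(run_pipeline(lib$agonist)))
  t1 <- summarize_table1(ds, with_diversity = FALSE)
  tot <- t1[t1$subset == "total", ]
  act <- t1[t1$subset == "active", ]
  ina <- t1[t1$subset == "inactive", ]
  expect_equal(act$n_compounds + ina$n_compounds, tot$n_compounds)
  expect_lte(tot$n_scaffolds, tot$n_compounds)
  expect_lte(tot$n_csk, tot$n_scaffolds)
})

test_that("table 2 category counts sum to the MMP totals", {
  lib <- small_lib()
  mmps <- list(
    agonist = generate_mmps(suppressWarnings(run_pipeline(lib$agonist))),
    antagonist = generate_mmps(suppressWarnings(run_pipeline(lib$antagonist)))
  )
  t2 <- summarize_table2(mmps)
  expect_equal(sum(t2$agonist), nrow(mmps$agonist))
  expect_equal(sum(t2$antagonist), nrow(mmps$antagonist))
  expect_equal(nrow(t2), 3L)
})

test_that("verify_reference_counts flags agreements and disagreements", {
  ref <- tibble::tibble(quantity = c("a", "b"), assay = "agonist",
                        value = c(1, 2))
  comp <- tibble::tibble(quantity = c("a", "b"), assay = "agonist",
                         value = c(1, 3))
  v <- verify_reference_counts(comp, ref)
  expect_equal(v$match, c(TRUE, FALSE))
  # missing computed quantities are reported unmatched, not dropped
  v2 <- verify_reference_counts(comp[1, ], ref)
  expect_equal(sum(v2$match), 1L)
  expect_equal(nrow(v2), 2L)
})

test_that("reference_counts is internally consistent", {
  ref <- reference_counts()
  val <- function(q, a) ref$value[ref$quantity == q & ref$assay == a]
  for (arm in c("agonist", "antagonist")) {
    expect_equal(val("n_active", arm) + val("n_inactive", arm),
                 val("cids_final", arm))
    expect_equal(val("n_inactive_mmps", arm) + val("n_active_mmps", arm) +
                   val("n_activity_cliffs", arm), val("n_mmps", arm))
    expect_lte(val("n_csk", arm), val("n_scaffolds", arm))
  }
  expect_equal(val("n_common", "combined") -
                 val("n_both_inactive_removed", "combined"),
               val("n_profiles", "combined"))
  expect_equal(val("n_same_moa", "combined") +
                 val("n_weak_cliffs", "combined") +
                 val("n_strong_cliffs", "combined"),
               val("n_moa_mmps", "combined"))
})

test_that("compute_study_counts round-trips through verify on the toy set", {
  t <- toy()
  counts <- compute_study_counts(t$agonist, t$antagonist)
  v <- verify_reference_counts(counts, reference = counts)
  expect_true(all(v$match))
})

test_that("plot constructors build renderable ggplot objects", {
  ds <- toy_clean()$agonist
  summ <- summarize_scaffolds(assign_scaffolds(ds))
  p1 <- ggplot2::autoplot(summ)
  p2 <- plot_audit(ds)
  prof <- drop_both_inactive(
    intersect_assays(ds, toy_clean()$antagonist))
  p3 <- ggplot2::autoplot(moa_mmp_pipeline(prof))
  for (p in list(p1, p2, p3)) {
    expect_s3_class(p, "ggplot")
    expect_no_error(ggplot2::ggplot_build(p))
  }
})
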