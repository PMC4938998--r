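test_that("ethylbenzene has exactly two single-cut fragmentations", {
  f <- enumerate_fragmentations("CCc1ccccc1")
  expect_equal(nrow(f), 2L)
  expect_setequal(f$core, canonical_smiles(c("[*]c1ccccc1", "[*]Cc1ccccc1")))
  expect_setequal(f$fragment, canonical_smiles(c("CC[*]", "C[*]")))
  # attachment points count zero heavy atoms; the parts conserve the total
  expect_true(all(f$core_heavy + f$frag_heavy == 8L))
})

test_that("ring bonds and non-single bonds are never cut", {
  expect_equal(nrow(enumerate_fragmentations("c1ccccc1")), 0L)   # all ring
  expect_equal(nrow(enumerate_fragmentations("C=C")), 0L)        # double bond
  expect_equal(nrow(enumerate_fragmentations("C")), 0L)          # no bond
  # styrene: only the ring-vinyl single bond is acyclic and single
  f <- enumerate_fragmentations("C=Cc1ccccc1")
  expect_equal(nrow(f), 1L)
  expect_equal(f$core, canonical_smiles("[*]c1ccccc1"))
})

test_that("a heavy-atom tie emits both orientations", {
  f <- enumerate_fragmentations("CCCO")  # central cut splits 2/2
  central <- f[f$core_heavy == f$frag_heavy, ]
  expect_equal(nrow(central), 2L)
  expect_setequal(central$core, canonical_smiles(c("[*]CC", "[*]CO")))
  expect_equal(sort(central$core), sort(central$fragment))
})

test_that("index_pairs emits each unordered compound pair once per core", {
  cmp <- tibble::tibble(cid = c("A", "B", "C"),
                        smiles = c("CCc1ccccc1", "OCc1ccccc1", "Cc1ccccc1"))
  pairs <- index_pairs(enumerate_fragmentations(cmp))
  expect_true(all(pairs$cid_left < pairs$cid_right))
  benz <- pairs[pairs$core == canonical_smiles("[*]c1ccccc1"), ]
  expect_equal(nrow(benz), 3L)  # all three share the benzene core
  # identical exchanged fragments never pair
  expect_true(all(pairs$frag_left != pairs$frag_right))
})

test_that("size_filter enforces inclusive boundaries with reasons", {
  mk <- function(core_heavy, fl, fr) {
    tibble::tibble(cid_left = "A", cid_right = "B", core = "x",
                   frag_left = "l", frag_right = "r",
                   core_heavy = core_heavy, frag_left_heavy = fl,
                   frag_right_heavy = fr, delta_heavy = abs(fl - fr),
                   n_cuts = 1L)
  }
  expect_true(size_filter(mk(26L, 13L, 13L))$retained)      # all at boundary
  expect_equal(size_filter(mk(25L, 13L, 13L))$reject_reason, "core_ratio")
  expect_equal(size_filter(mk(28L, 14L, 13L))$reject_reason, "frag_size")
  expect_equal(size_filter(mk(26L, 13L, 4L))$reject_reason, "delta")
  expect_true(size_filter(mk(26L, 13L, 5L))$retained)       # delta exactly 8
})

test_that("deduplicate_pairs keeps one cut per compound pair, count seed-independent", {
  cmp <- run_pipeline(small_lib()$agonist)
  cand <- size_filter(index_pairs(enumerate_fragmentations(cmp)))
  d1 <- deduplicate_pairs(cand, seed = 1)
  d2 <- deduplicate_pairs(cand, seed = 99)
  expect_equal(nrow(d1), dplyr::n_distinct(pair_key(d1$cid_left, d1$cid_right)))
  expect_equal(nrow(d1), nrow(d2))
  expect_setequal(pair_key(d1$cid_left, d1$cid_right),
                  pair_key(d2$cid_left, d2$cid_right))
  # the representative is a minimal-delta cut
  mins <- cand[cand$retained, ] |>
    dplyr::group_by(cid_left, cid_right) |>
    dplyr::summarise(m = min(delta_heavy), .groups = "drop") |>
    dplyr::inner_join(d1, by = c("cid_left", "cid_right"))
  expect_true(all(mins$delta_heavy == mins$m))
  # same seed reproduces the identical table
  expect_equal(d1, deduplicate_pairs(cand, seed = 1))
})

test_that("classify_pairs maps binary outcome combinations and validates", {
  pairs <- tibble::tibble(cid_left = c("a", "a", "b"),
                          cid_right = c("b", "c", "c"))
  outc <- tibble::tibble(cid = c("a", "b", "c"),
                         outcome = c("Active", "Active", "Inactive"))
  out <- classify_pairs(pairs, outc)
  expect_equal(out$category, c("active_mmp", "activity_cliff",
                               "activity_cliff"))
  expect_error(classify_pairs(pairs, outc[1:2, ]), "binary outcome")
})

test_that("generate_mmps matches a brute-force pairwise oracle on the toy set", {
  ds <- toy_clean()$agonist
  mmps <- generate_mmps(ds)
  # oracle: compare every unordered pair of compounds directly, without the
  # core index: a pair is an MMP iff some fragmentation of each yields the
  # same core with different fragments, passing the size rules
  frs <- lapply(seq_len(nrow(ds)), function(i) {
    enumerate_fragmentations(ds[i, c("cid", "smiles")])
  })
  found <- character()
  for (i in seq_len(nrow(ds) - 1)) {
    for (j in (i + 1):nrow(ds)) {
      m <- dplyr::inner_join(frs[[i]], frs[[j]],
                             by = c("core", "core_heavy", "n_cuts"),
                             relationship = "many-to-many")
      m <- m[m$fragment.x != m$fragment.y, ]
      ok <- m$core_heavy >= 2 * pmax(m$frag_heavy.x, m$frag_heavy.y) &
        pmax(m$frag_heavy.x, m$frag_heavy.y) <= 13 &
        abs(m$frag_heavy.x - m$frag_heavy.y) <= 8
      if (any(ok)) found <- c(found, pair_key(ds$cid[i], ds$cid[j]))
    }
  }
  expect_setequal(pair_key(mmps$cid_left, mmps$cid_right), found)
})

test_that("build_network and write_network emit both formats", {
  ds <- toy_clean()$agonist
  mmps <- generate_mmps(ds)
  g <- build_network(mmps, ds)
  expect_s3_class(g, "igraph")
  expect_equal(igraph::ecount(g), nrow(mmps))
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(g, gml, "graphml")
  write_network(g, sif, "sif")
  expect_true(file.size(gml) > 0)
  lines <- readLines(sif)
  expect_equal(length(lines), nrow(mmps))
  expect_true(all(grepl("\t", lines)))
})

test_that("double-cut mode finds linker exchanges single cuts cannot", {
  cmp <- tibble::tibble(
    cid = c("L1", "L2"),
    smiles = c("c1ccccc1COCc1ccncc1", "c1ccccc1CCCCc1ccncc1")
  )
  p1 <- deduplicate_pairs(size_filter(index_pairs(
    enumerate_fragmentations(cmp, max_cuts = 1L))))
  p2 <- deduplicate_pairs(size_filter(index_pairs(
    enumerate_fragmentations(cmp, max_cuts = 2L))))
  # the two benzyl/pyridyl ends are identical; only exchanging the inner
  # linker (-COC- vs -CCCC-) matches them
  expect_equal(nrow(p1), 0L)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$n_cuts, 2L)
})
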