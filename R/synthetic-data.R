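# Seeded synthetic screening libraries with planted ground truth.
#
# Compounds are built by attaching a small single-bonded substituent prefix
# to a ring-system template; all members of one template series share the
# template as invariant core, so the full matched-pair list, the activity
# cliffs and the MOA categories are enumerable analytically at generation
# time, without running the MMP machinery. Curation artifacts (missing
# readouts, duplicate substances, discrepant compounds, non-binary
# outcomes, mixtures, acyclic decoys) are injected on dedicated decoy
# compounds, so each is removed by exactly one curation stage.

# substituent vocabulary: SMILES prefixes that attach to a template's first
# atom via one single bond; names carry nothing, values are heavy-atom counts
SUBSTITUENT_VOCAB <- c(
  "C" = 1, "CC" = 2, "CCC" = 3, "CCCC" = 4,
  "CC(C)" = 3, "CC(C)C" = 4, "CC(C)(C)" = 4,
  "OC" = 2, "OCC" = 3, "OCCC" = 4, "OC(C)" = 3,
  "NC" = 2, "NCC" = 3, "NCCC" = 4, "NC(C)" = 3,
  "COC" = 3, "CCOC" = 4, "COCC" = 4,
  "FC" = 2, "FCC" = 3, "FC(F)(F)" = 4,
  "ClC" = 2, "ClCC" = 3,
  "BrC" = 2, "BrCC" = 3
)

# fused-bicyclic template grammar: four skeleton patterns x heteroaromatic
# substitutions of the second ring; every template's first atom carries a
# free hydrogen so a substituent prefix can attach there
#' @noRd
template_pool <- function() {
  slots <- expand.grid(a = c("c", "n"), b = c("c", "n"),
                       c = c("c", "n"), d = c("c", "n"),
                       stringsAsFactors = FALSE)
  slots <- slots[rowSums(slots == "n") <= 2L, , drop = FALSE]
  pats <- c(
    naphthalene = "c1ccc2%s%s%s%sc2c1",   # 6-6 aromatic, 10 heavy
    tetralin = "C1CCc2%s%s%s%sc2C1",      # 6-6 half-saturated, 10 heavy
    indane = "C1Cc2%s%s%s%sc2C1",         # 6-5, 9 heavy
    isochroman = "C1COc2%s%s%s%sc2C1",    # 6-6 with ring O, 10 heavy
    dihydrobenzofuran = "C1Oc2%s%s%s%sc2C1",      # 6-5 with ring O, 9 heavy
    tetrahydroquinoline = "C1CNc2%s%s%s%sc2C1",   # 6-6 with ring N, 10 heavy
    benzosuberane = "C1CCCc2%s%s%s%sc2C1"         # 6-7, 11 heavy
  )
  skel <- c(naphthalene = "66", tetralin = "66", indane = "65",
            isochroman = "66", dihydrobenzofuran = "65",
            tetrahydroquinoline = "66", benzosuberane = "67")
  smi <- character()
  cls <- character()
  for (p in names(pats)) {
    s <- sprintf(pats[[p]], slots$a, slots$b, slots$c, slots$d)
    smi <- c(smi, s)
    cls <- c(cls, rep(skel[[p]], length(s)))
  }
  can <- smiles_to_cansmi(smi)
  ok <- !is.na(can) & !duplicated(can)
  tibble::tibble(template = smi[ok], canonical = can[ok],
                 skeleton_class = cls[ok],
                 heavy = vapply(mols_from_smiles(smi[ok]), mol_n_heavy,
                                integer(1)))
}

#' Configuration for a synthetic paired-screen library
#'
#' The defaults describe the emulated study conditions: a library of 500
#' ring-system series over ~50 scaffold templates screened in an agonist
#' and an antagonist arm, active fractions matching a typical imbalanced
#' HTS readout (about 4% agonist, 9% antagonist actives), a handful of
#' planted dual-action compounds and MOA-cliff pairs, and curation
#' artifacts injected at low rates.
#'
#' @param seed Integer seed; the library is a pure function of the config.
#' @param n_scaffold_templates,n_compounds Library dimensions.
#' @param substituent_vocabulary Named numeric vector: SMILES prefix ->
#'   heavy-atom count; every fragment must have at most 13 heavy atoms.
#' @param fraction_active_agonist,fraction_active_antagonist Active
#'   proportions per assay (disjointly assigned to non-planted compounds).
#' @param n_dual_active Planted compounds active in both assays.
#' @param n_planted_strong_cliffs,n_planted_weak_cliffs Planted MOA-cliff
#'   pairs, each in a dedicated two-member series.
#' @param artifact_rates Named list of proportions of `n_compounds`:
#'   `missing`, `duplicate_sid`, `discrepant`, `inconclusive`, `mixture`,
#'   `acyclic`.
#' @param potency_range pIC50 range (molar) from which active potencies are
#'   drawn log-uniformly.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_scaffold_templates = 50L,
                              n_compounds = 500L,
                              substituent_vocabulary = SUBSTITUENT_VOCAB,
                              fraction_active_agonist = 0.041,
                              fraction_active_antagonist = 0.090,
                              n_dual_active = 6L,
                              n_planted_strong_cliffs = 2L,
                              n_planted_weak_cliffs = 3L,
                              artifact_rates = list(
                                missing = 0.01, duplicate_sid = 0.05,
                                discrepant = 0.02, inconclusive = 0.05,
                                mixture = 0.10, acyclic = 0.05
                              ),
                              potency_range = c(4.2, 9.2)) {
  cfg <- list(
    seed = as.integer(seed),
    n_scaffold_templates = as.integer(n_scaffold_templates),
    n_compounds = as.integer(n_compounds),
    substituent_vocabulary = substituent_vocabulary,
    fraction_active_agonist = fraction_active_agonist,
    fraction_active_antagonist = fraction_active_antagonist,
    n_dual_active = as.integer(n_dual_active),
    n_planted_strong_cliffs = as.integer(n_planted_strong_cliffs),
    n_planted_weak_cliffs = as.integer(n_planted_weak_cliffs),
    artifact_rates = artifact_rates,
    potency_range = potency_range
  )
  fracs <- c(cfg$fraction_active_agonist, cfg$fraction_active_antagonist,
             unlist(cfg$artifact_rates))
  if (any(fracs < 0 | fracs > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$fraction_active_agonist + cfg$fraction_active_antagonist > 1) {
    stop("active fractions must sum to at most 1", call. = FALSE)
  }
  counts <- c(cfg$n_scaffold_templates, cfg$n_compounds, cfg$n_dual_active,
              cfg$n_planted_strong_cliffs, cfg$n_planted_weak_cliffs)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(cfg$substituent_vocabulary > 13)) {
    stop("substituent fragments must have at most 13 heavy atoms",
         call. = FALSE)
  }
  n_dedicated <- cfg$n_dual_active +
    2L * (cfg$n_planted_strong_cliffs + cfg$n_planted_weak_cliffs)
  n_series_dedicated <- cfg$n_dual_active + cfg$n_planted_strong_cliffs +
    cfg$n_planted_weak_cliffs
  if (n_dedicated > cfg$n_compounds) {
    stop("more planted compounds than n_compounds", call. = FALSE)
  }
  if (n_series_dedicated >= cfg$n_scaffold_templates) {
    stop("not enough scaffold templates for the planted series", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic paired-screen library with ground truth
#'
#' Deterministic for a fixed config (byte-identical outputs for equal
#' seeds). Returns the raw agonist and antagonist datasets (before
#' curation) and a `truth` list holding, among others: per-compound true
#' scaffolds and skeleton classes, the complete matched-pair list with
#' per-assay categories, the MOA pair list, the planted dual/strong/weak
#' identities, and the expected per-stage audit removals.
#'
#' @param config A [simulation_config()].
#' @return List with elements `agonist`, `antagonist` (raw `assay_tbl`) and
#'   `truth`.
#' @export
generate_library <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, generate_library_impl(config))
}

#' @noRd
generate_library_impl <- function(cfg) {
  pool <- template_pool()
  if (nrow(pool) < cfg$n_scaffold_templates) {
    stop("template grammar yields only ", nrow(pool), " templates",
         call. = FALSE)
  }
  templates <- pool[seq_len(cfg$n_scaffold_templates), ]
  vocab <- cfg$substituent_vocabulary

  ns <- cfg$n_planted_strong_cliffs
  nw <- cfg$n_planted_weak_cliffs
  nd <- cfg$n_dual_active
  n_rest <- cfg$n_compounds - nd - 2L * (ns + nw)

  # series plan: dedicated templates first, then roughly equal series
  kind <- c(rep("strong", ns), rep("weak", nw), rep("dual", nd))
  sizes <- c(rep(2L, ns + nw), rep(1L, nd))
  m <- cfg$n_scaffold_templates - length(sizes)
  base <- n_rest %/% m
  rest_sizes <- rep(base, m) + (seq_len(m) <= n_rest %% m)
  rest_sizes <- rest_sizes[rest_sizes > 0L]
  if (any(rest_sizes > length(vocab))) {
    stop("series larger than the substituent vocabulary; increase ",
         "n_scaffold_templates or the vocabulary", call. = FALSE)
  }
  kind <- c(kind, rep("plain", length(rest_sizes)))
  sizes <- c(sizes, rest_sizes)

  compounds <- purrr::map_dfr(seq_along(sizes), function(s) {
    subs <- sample(names(vocab), sizes[s])
    tibble::tibble(
      series_id = s,
      series_kind = kind[s],
      member = seq_len(sizes[s]),
      template = templates$template[s],
      scaffold = templates$canonical[s],
      skeleton_class = templates$skeleton_class[s],
      substituent = subs,
      smiles = paste0(subs, templates$template[s])
    )
  })
  compounds$cid <- sprintf("CID%05d", seq_len(nrow(compounds)))
  compounds$sid <- sprintf("SID%05d", seq_len(nrow(compounds)))

  # outcomes: planted patterns first, then disjoint random single-assay
  # activity at the configured fractions
  u <- stats::runif(nrow(compounds))
  fa <- cfg$fraction_active_agonist
  fb <- cfg$fraction_active_antagonist
  compounds <- compounds |>
    dplyr::mutate(
      agonist_outcome = dplyr::case_when(
        series_kind == "strong" & member == 1L ~ "Active",
        series_kind == "strong" & member == 2L ~ "Inactive",
        series_kind == "weak" & member == 1L ~ "Active",
        series_kind == "weak" & member == 2L ~ "Active",
        series_kind == "dual" ~ "Active",
        u < fa ~ "Active",
        TRUE ~ "Inactive"
      ),
      antagonist_outcome = dplyr::case_when(
        series_kind == "strong" & member == 1L ~ "Inactive",
        series_kind == "strong" & member == 2L ~ "Active",
        series_kind == "weak" & member == 1L ~ "Active",
        series_kind == "weak" & member == 2L ~ "Inactive",
        series_kind == "dual" ~ "Active",
        u >= fa & u < fa + fb ~ "Active",
        TRUE ~ "Inactive"
      ),
      label_set = moa_label(.data$agonist_outcome, .data$antagonist_outcome)
    )

  # potencies: log-uniform pIC50 over the configured range for actives
  pr <- cfg$potency_range
  pic_ag <- ifelse(compounds$agonist_outcome == "Active",
                   stats::runif(nrow(compounds), pr[1], pr[2]), NA_real_)
  pic_an <- ifelse(compounds$antagonist_outcome == "Active",
                   stats::runif(nrow(compounds), pr[1], pr[2]), NA_real_)

  # decoys carrying the curation artifacts; substituent chains of >= 5
  # carbons keep them distinct from every clean compound
  rates <- cfg$artifact_rates
  n_art <- vapply(rates[c("missing", "discrepant", "inconclusive",
                          "mixture", "acyclic")],
                  function(r) as.integer(round(r * cfg$n_compounds)),
                  integer(1))
  n_decoy_ring <- sum(n_art[c("missing", "discrepant", "inconclusive",
                              "mixture")])
  decoy_ring <- if (n_decoy_ring > 0L) {
    idx <- seq_len(n_decoy_ring) - 1L
    paste0(strrep("C", 5L + idx %/% nrow(pool)),
           pool$template[idx %% nrow(pool) + 1L])
  } else character()
  decoy_kind <- rep(c("missing", "discrepant", "inconclusive", "mixture"),
                    n_art[c("missing", "discrepant", "inconclusive",
                            "mixture")])
  acyclic <- if (n_art[["acyclic"]] > 0L) {
    strrep("C", 4L + seq_len(n_art[["acyclic"]]))
  } else character()
  decoys <- tibble::tibble(
    smiles = c(
      ifelse(decoy_kind == "mixture", paste0(decoy_ring, ".Cl"), decoy_ring),
      acyclic
    ),
    kind = c(decoy_kind, rep("acyclic", n_art[["acyclic"]]))
  )
  decoys$cid <- sprintf("CIDD%04d", seq_len(nrow(decoys)))
  decoys$sid <- sprintf("SIDD%04d", seq_len(nrow(decoys)))

  n_dup <- as.integer(round(rates$duplicate_sid * cfg$n_compounds))
  dup_idx <- if (n_dup > 0L) sample(nrow(compounds), min(n_dup, nrow(compounds)))
             else integer()

  build_assay <- function(outcome_col, pic, source_assay) {
    clean <- tibble::tibble(
      sid = compounds$sid,
      cid = compounds$cid,
      smiles = compounds$smiles,
      outcome = compounds[[outcome_col]],
      potencies = purrr::map(pic, ~ if (is.na(.x)) numeric() else
        signif(10^(6 - .x), 8)),
      source_assay = source_assay
    )
    dup <- clean[dup_idx, ]
    if (nrow(dup)) {
      dup$sid <- paste0(dup$sid, "b")
      # a second reading within one log order of the first
      dup$potencies <- purrr::map2(dup$potencies, seq_len(nrow(dup)), ~ {
        if (!length(.x)) return(numeric())
        signif(.x * 10^(0.3 * ((.y %% 2) * 2 - 1)), 8)
      })
    }
    dk <- decoys$kind
    drec <- tibble::tibble(
      sid = decoys$sid,
      cid = decoys$cid,
      smiles = decoys$smiles,
      outcome = dplyr::case_when(
        dk == "missing" ~ "Missing",
        dk == "inconclusive" ~ "Other",
        TRUE ~ "Inactive"
      ),
      potencies = rep(list(numeric()), nrow(decoys)),
      source_assay = source_assay
    )
    disc <- drec[dk == "discrepant", ]
    if (nrow(disc)) {
      disc$sid <- paste0(disc$sid, "b")
      disc$outcome <- "Active"
    }
    as_assay_tbl(dplyr::bind_rows(clean, dup, drec, disc),
                 source_assay = source_assay)
  }

  agonist <- build_assay("agonist_outcome", pic_ag, "agonist")
  antagonist <- build_assay("antagonist_outcome", pic_an, "antagonist")

  # analytic ground truth ---------------------------------------------------
  pair_tbl <- compounds |>
    dplyr::group_by(.data$series_id) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2L) return(tibble::tibble())
      cmb <- utils::combn(order(g$cid), 2L)
      tibble::tibble(
        i = cmb[1, ], j = cmb[2, ],
        cid_left = g$cid[cmb[1, ]], cid_right = g$cid[cmb[2, ]],
        sub_left = g$substituent[cmb[1, ]],
        sub_right = g$substituent[cmb[2, ]],
        ag_l = g$agonist_outcome[cmb[1, ]], ag_r = g$agonist_outcome[cmb[2, ]],
        an_l = g$antagonist_outcome[cmb[1, ]],
        an_r = g$antagonist_outcome[cmb[2, ]],
        lab_l = g$label_set[cmb[1, ]], lab_r = g$label_set[cmb[2, ]],
        template = g$template[1]
      )
    }) |>
    dplyr::ungroup()
  cat_of <- function(l, r) {
    dplyr::case_when(
      l == "Inactive" & r == "Inactive" ~ "inactive_mmp",
      l == "Active" & r == "Active" ~ "active_mmp",
      TRUE ~ "activity_cliff"
    )
  }
  mmp_truth <- pair_tbl |>
    dplyr::transmute(
      cid_left = .data$cid_left, cid_right = .data$cid_right,
      series_id = .data$series_id,
      core = paste0("[*]", .data$template),
      frag_left = paste0(.data$sub_left, "[*]"),
      frag_right = paste0(.data$sub_right, "[*]"),
      category_agonist = cat_of(.data$ag_l, .data$ag_r),
      category_antagonist = cat_of(.data$an_l, .data$an_r)
    )
  mmp_truth$core <- smiles_to_cansmi(mmp_truth$core)
  mmp_truth$frag_left <- smiles_to_cansmi(mmp_truth$frag_left)
  mmp_truth$frag_right <- smiles_to_cansmi(mmp_truth$frag_right)
  moa_truth <- pair_tbl |>
    dplyr::filter(!is.na(.data$lab_l), !is.na(.data$lab_r)) |>
    dplyr::transmute(
      cid_left = .data$cid_left, cid_right = .data$cid_right,
      moa_category = dplyr::case_when(
        lab_l == lab_r ~ "same_moa",
        lab_l == "dual" | lab_r == "dual" ~ "weak_cliff",
        TRUE ~ "strong_cliff"
      )
    )
  planted <- compounds |>
    dplyr::filter(.data$series_kind %in% c("strong", "weak")) |>
    dplyr::group_by(.data$series_id) |>
    dplyr::summarise(kind = .data$series_kind[1],
                     cid_left = min(.data$cid), cid_right = max(.data$cid),
                     .groups = "drop")
  audit_expected <- tibble::tibble(
    stage = PIPELINE_STAGES,
    n_removed = c(n_art[["missing"]], 0L, n_art[["discrepant"]],
                  n_art[["inconclusive"]], n_art[["mixture"]],
                  n_art[["acyclic"]])
  )
  truth <- list(
    compounds = compounds,
    mmp_pairs = mmp_truth,
    moa_pairs = moa_truth,
    dual_cids = compounds$cid[compounds$series_kind == "dual"],
    strong_pairs = planted[planted$kind == "strong",
                           c("cid_left", "cid_right")],
    weak_pairs = planted[planted$kind == "weak", c("cid_left", "cid_right")],
    potency = tibble::tibble(
      cid = rep(compounds$cid, 2),
      assay = rep(c("agonist", "antagonist"), each = nrow(compounds)),
      pic50 = c(pic_ag, pic_an)
    ) |> dplyr::filter(!is.na(.data$pic50)),
    audit_expected = audit_expected,
    decoys = decoys,
    duplicated_cids = compounds$cid[dup_idx],
    config = cfg
  )
  list(agonist = agonist, antagonist = antagonist, truth = truth)
}

#' A small hand-written paired-assay fixture
#'
#' Embeds worked structures at tiny scale: a steroid whose Bemis-Murcko
#' scaffold is the 4-ring ketone "O=C1CCC2C(=C1)CCC1C2CCC2C1CCC2", a
#' synthetic polar/apolar analog pair planted as a strong MOA-cliff, a
#' dual-action analog (weak MOA-cliff partner), potency lists exercising
#' the mean and drop branches of the aggregation rule, and one artifact for
#' each curation stage.
#'
#' @return List with raw `agonist` and `antagonist` datasets and a `truth`
#'   list naming the planted scaffold string, cliff pair and dual compound.
#' @export
toy_assay_fixture <- function() {
  sca1 <- "O=C1CCC2C(=C1)CCC1C2CCC2C1CCC2"
  sca2 <- "O=C1CCC2C(=C1)CCC1C2CCC2C1C=CC2"
  steroid <- "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O"
  strong_a <- "OCCc1ccc2ccccc2c1"  # polar tail, agonist
  strong_b <- "CCCc1ccc2ccccc2c1"  # apolar tail, antagonist
  dual <- "NCc1ccc2ccccc2c1"       # dual action, same series
  plain <- "Cc1ccc2ccccc2c1"       # inactive everywhere
  rec <- function(sid, cid, smiles, outcome, pot = numeric()) {
    tibble::tibble(sid = sid, cid = cid, smiles = smiles, outcome = outcome,
                   potencies = list(pot))
  }
  ag <- dplyr::bind_rows(
    rec("S1", "10631", steroid, "Active", 0.01),          # pIC50 8
    rec("S2", "3033968", sca2, "Active", c(1.0, 10^-0.5)),# mean 6.25
    rec("S3", "C_STRONG_A", strong_a, "Active", 20.4),    # ~4.69
    rec("S4", "C_STRONG_B", strong_b, "Inactive"),
    rec("S5", "C_DUAL", dual, "Active", c(10, 0.1)),      # spread 2: dropped
    rec("S6", "C_PLAIN", plain, "Inactive"),
    rec("S6b", "C_PLAIN", plain, "Inactive"),             # duplicate SID
    rec("S7", "C_DISC", "OCc1ccccc1", "Active"),
    rec("S7b", "C_DISC", "OCc1ccccc1", "Inactive"),       # discrepant
    rec("S8", "C_MIX", "CCOc1ccccc1.Cl", "Inactive"),     # mixture
    rec("S9", "C_ACYC", "CCCCCC", "Inactive"),            # acyclic
    rec("S10", "C_MISS", "Clc1ccccc1", "Missing"),        # missing readout
    rec("S11", "C_INCONCL", "Brc1ccccc1", "Other")        # inconclusive
  )
  an <- ag |>
    dplyr::mutate(
      outcome = dplyr::case_when(
        cid == "C_STRONG_A" ~ "Inactive",
        cid == "C_STRONG_B" ~ "Active",
        cid %in% c("10631", "3033968") ~ "Inactive",
        TRUE ~ .data$outcome
      ),
      potencies = dplyr::if_else(
        .data$cid == "C_STRONG_B", list(17.0),  # ~4.77
        dplyr::if_else(.data$cid %in% c("10631", "3033968"),
                       list(numeric()), .data$potencies))
    )
  list(
    agonist = as_assay_tbl(dplyr::mutate(ag, source_assay = "agonist"),
                           source_assay = "agonist"),
    antagonist = as_assay_tbl(dplyr::mutate(an, source_assay = "antagonist"),
                              source_assay = "antagonist"),
    truth = list(
      sca1 = sca1, sca2 = sca2, steroid_cid = "10631",
      strong_pair = c("C_STRONG_A", "C_STRONG_B"),
      dual_cid = "C_DUAL",
      potency_dropped_cid = "C_DUAL",
      n_clean = 6L
    )
  )
}
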