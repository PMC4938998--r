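# End-to-end orchestration: curation -> scaffolds -> diversity -> MMPs ->
# MOA, emitting the summary tables, histogram data, networks and a run
# manifest with file checksums.

#' Reference counts of the original paired androgen-receptor screens
#'
#' The headline counts reported for the deposited Tox21 AR agonist
#' (AID 743053) and antagonist (AID 743063) screens, used as reference
#' inputs by [verify_reference_counts()] when a user supplies local copies
#' of those deposits. Reproducing them requires the real data; they are not
#' computed by this package.
#'
#' @return Tibble with `quantity`, `assay` (`agonist`, `antagonist` or
#'   `combined`) and `value`.
#' @export
reference_counts <- function() {
  tibble::tribble(
    ~quantity, ~assay, ~value,
    "cids_final", "agonist", 4162,
    "n_active", "agonist", 172,
    "n_inactive", "agonist", 3990,
    "n_scaffolds", "agonist", 1571,
    "n_scaffolds_active", "agonist", 72,
    "n_scaffolds_inactive", "agonist", 1521,
    "n_csk", "agonist", 895,
    "n_csk_active", "agonist", 53,
    "n_csk_inactive", "agonist", 865,
    "n_mmps", "agonist", 9695,
    "n_inactive_mmps", "agonist", 9462,
    "n_active_mmps", "agonist", 141,
    "n_activity_cliffs", "agonist", 92,
    "cids_final", "antagonist", 3563,
    "n_active", "antagonist", 322,
    "n_inactive", "antagonist", 3241,
    "n_scaffolds", "antagonist", 1384,
    "n_scaffolds_active", "antagonist", 198,
    "n_scaffolds_inactive", "antagonist", 1248,
    "n_csk", "antagonist", 814,
    "n_csk_active", "antagonist", 160,
    "n_csk_inactive", "antagonist", 717,
    "n_mmps", "antagonist", 8049,
    "n_inactive_mmps", "antagonist", 7623,
    "n_active_mmps", "antagonist", 94,
    "n_activity_cliffs", "antagonist", 332,
    "n_common", "combined", 3293,
    "n_both_inactive_removed", "combined", 3008,
    "n_profiles", "combined", 285,
    "n_opposite", "combined", 240,
    "n_dual", "combined", 45,
    "n_moa_mmps", "combined", 78,
    "n_same_moa", "combined", 64,
    "n_weak_cliffs", "combined", 13,
    "n_strong_cliffs", "combined", 1
  )
}

#' Compute the study's headline counts for a pair of raw datasets
#'
#' Runs curation, scaffold/CSK decomposition, MMP generation and the MOA
#' pipeline, and reports the counts in the vocabulary of
#' [reference_counts()].
#'
#' @param agonist,antagonist Raw `assay_tbl` datasets.
#' @param seed Seed for the MMP deduplication tie-break.
#' @param max_cuts Fragmentation mode (see [enumerate_fragmentations()]).
#' @return Tibble with `quantity`, `assay`, `value`.
#' @export
compute_study_counts <- function(agonist, antagonist, seed = 1L,
                                 max_cuts = 1L) {
  per_assay <- function(raw, assay) {
    ds <- run_pipeline(raw)
    asg <- assign_scaffolds(ds)
    mmps <- generate_mmps(ds, max_cuts = max_cuts, seed = seed)
    cat_n <- function(x) sum(mmps$category == x)
    tibble::tibble(
      quantity = c("cids_final", "n_active", "n_inactive", "n_scaffolds",
                   "n_scaffolds_active", "n_scaffolds_inactive", "n_csk",
                   "n_csk_active", "n_csk_inactive", "n_mmps",
                   "n_inactive_mmps", "n_active_mmps", "n_activity_cliffs"),
      assay = assay,
      value = c(
        dplyr::n_distinct(ds$cid),
        sum(ds$outcome == "Active"),
        sum(ds$outcome == "Inactive"),
        dplyr::n_distinct(asg$scaffold),
        dplyr::n_distinct(asg$scaffold[asg$outcome == "Active"]),
        dplyr::n_distinct(asg$scaffold[asg$outcome == "Inactive"]),
        dplyr::n_distinct(asg$csk),
        dplyr::n_distinct(asg$csk[asg$outcome == "Active"]),
        dplyr::n_distinct(asg$csk[asg$outcome == "Inactive"]),
        nrow(mmps),
        cat_n("inactive_mmp"), cat_n("active_mmp"), cat_n("activity_cliff")
      ),
      ds = list(ds)
    )
  }
  ag <- per_assay(agonist, "agonist")
  an <- per_assay(antagonist, "antagonist")
  profiles_all <- intersect_assays(ag$ds[[1]], an$ds[[1]])
  profiles <- drop_both_inactive(profiles_all)
  moa <- if (nrow(profiles) >= 2L) {
    moa_mmp_pipeline(profiles, max_cuts = max_cuts, seed = seed)
  } else {
    structure(list(pairs = tibble::tibble(moa_category = character()),
                   summary = tibble::tibble()), class = "moa_result")
  }
  comb <- tibble::tibble(
    quantity = c("n_common", "n_both_inactive_removed", "n_profiles",
                 "n_opposite", "n_dual", "n_moa_mmps", "n_same_moa",
                 "n_weak_cliffs", "n_strong_cliffs"),
    assay = "combined",
    value = c(
      nrow(profiles_all),
      nrow(profiles_all) - nrow(profiles),
      nrow(profiles),
      sum(profiles$label_set %in% c("agonist", "antagonist")),
      sum(profiles$label_set == "dual"),
      nrow(moa$pairs),
      sum(moa$pairs$moa_category == "same_moa"),
      sum(moa$pairs$moa_category == "weak_cliff"),
      sum(moa$pairs$moa_category == "strong_cliff")
    )
  )
  dplyr::bind_rows(ag[, c("quantity", "assay", "value")],
                   an[, c("quantity", "assay", "value")], comb)
}

#' Compare computed counts against a reference table
#'
#' Intended for users holding local copies of the original deposits: run
#' [compute_study_counts()] on them and compare against
#' [reference_counts()]. Works with any reference in the same shape, so the
#' comparison machinery is itself testable on synthetic ground truth.
#'
#' @param computed,reference Tibbles with `quantity`, `assay`, `value`.
#' @return The joined table with `value_computed`, `value_reference` and a
#'   logical `match` column.
#' @export
verify_reference_counts <- function(computed, reference = reference_counts()) {
  dplyr::full_join(
    dplyr::rename(reference, value_reference = "value"),
    dplyr::rename(computed, value_computed = "value"),
    by = c("quantity", "assay")
  ) |>
    dplyr::mutate(match = !is.na(.data$value_computed) &
                    !is.na(.data$value_reference) &
                    .data$value_computed == .data$value_reference)
}

#' Diversity index per outcome group
#'
#' @param ds A curated `assay_tbl`.
#' @param method Passed to [diversity_index()].
#' @param max_set Exact all-pairs computation is retained up to this many
#'   members (the emulated screens stay below 4000).
#' @return Tibble with `outcome`, `n`, `di`, `dialect`.
#' @export
outcome_diversity <- function(ds, method = "pairwise", max_set = 5000L) {
  ds |>
    tibble::as_tibble() |>
    dplyr::filter(.data$outcome %in% c("Active", "Inactive")) |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(
      n = dplyr::n(),
      di = if (dplyr::n() < 2L) NA_real_ else {
        if (dplyr::n() > max_set) {
          stop("set larger than max_set; raise the cap deliberately",
               call. = FALSE)
        }
        diversity_index(fingerprint(.data$smiles), method = method)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(dialect = "FP2")
}

#' Table-1-style summary of a curated assay pair
#'
#' Unique compound, scaffold and CSK counts and the diversity index, split
#' total/active/inactive per assay.
#'
#' @param datasets Named list of curated `assay_tbl` (e.g.
#'   `list(agonist = ..., antagonist = ...)`).
#' @param with_diversity Compute fingerprints and DI (slower).
#' @return Long tibble: `assay`, `subset`, `n_compounds`, `n_scaffolds`,
#'   `n_csk`, `diversity_index`.
#' @export
summarize_table1 <- function(datasets, with_diversity = TRUE) {
  purrr::imap_dfr(datasets, function(ds, assay) {
    asg <- assign_scaffolds(ds)
    di <- if (with_diversity) outcome_diversity(ds) else NULL
    purrr::map_dfr(c("total", "Active", "Inactive"), function(sub) {
      part <- if (sub == "total") asg else dplyr::filter(asg, .data$outcome == sub)
      tibble::tibble(
        assay = assay,
        subset = tolower(sub),
        n_compounds = dplyr::n_distinct(part$cid),
        n_scaffolds = dplyr::n_distinct(part$scaffold),
        n_csk = dplyr::n_distinct(part$csk),
        diversity_index = if (sub == "total" || is.null(di)) NA_real_ else
          di$di[match(sub, di$outcome)]
      )
    })
  })
}

#' Table-2-style MMP category counts per assay
#'
#' @param mmps_list Named list of classified MMP tibbles per assay.
#' @return Tibble `category` x assay counts (categories partition totals).
#' @export
summarize_table2 <- function(mmps_list) {
  purrr::imap_dfr(mmps_list, function(m, assay) {
    tibble::tibble(assay = assay,
                   category = factor(m$category,
                                     c("inactive_mmp", "active_mmp",
                                       "activity_cliff"))) |>
      dplyr::count(.data$assay, .data$category, .drop = FALSE)
  }) |>
    tidyr::pivot_wider(names_from = "assay", values_from = "n")
}

#' Run the full pipeline and write every output table
#'
#' Curates both arms, computes scaffold/CSK statistics, ring histograms,
#' exclusive-scaffold potency profiles, diversity indices, per-assay MMPs
#' and networks, and the combined MOA analysis; writes them as CSV (plus
#' GraphML/SIF networks) under `out_dir` and returns a manifest listing
#' every file with an md5 checksum.
#'
#' @param agonist,antagonist Raw `assay_tbl` datasets.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for MMP deduplication.
#' @param max_cuts Fragmentation mode.
#' @param with_diversity Compute diversity indices (slower).
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_all <- function(agonist, antagonist, out_dir, seed = 1L, max_cuts = 1L,
                    with_diversity = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_table(x, path)
    files <<- c(files, path)
  }
  stages <- list()
  datasets <- list()
  mmps_list <- list()
  for (assay in c("agonist", "antagonist")) {
    raw <- if (assay == "agonist") agonist else antagonist
    ds <- run_pipeline(raw)
    datasets[[assay]] <- ds
    emit(audit_trail(ds), paste0("audit_", assay, ".csv"))
    emit(tibble::as_tibble(ds)[, c("sid", "cid", "smiles", "outcome")],
         paste0("clean_", assay, ".csv"))
    asg <- assign_scaffolds(ds)
    emit(asg, paste0("scaffolds_", assay, ".csv"))
    summ <- summarize_scaffolds(asg)
    emit(summ$ring_histogram, paste0("fig1_hist_", assay, ".csv"))
    pot <- aggregate_potencies(ds)
    emit(exclusive_potency_profile(summ, asg, pot),
         paste0("exclusive_scaffolds_", assay, ".csv"))
    mmps <- generate_mmps(ds, max_cuts = max_cuts, seed = seed)
    mmps_list[[assay]] <- mmps
    emit(mmps[, c("cid_left", "cid_right", "core", "frag_left", "frag_right",
                  "delta_heavy", "category")], paste0("mmps_", assay, ".csv"))
    net <- build_network(mmps)
    gml <- file.path(out_dir, paste0("network_", assay, ".graphml"))
    sif <- file.path(out_dir, paste0("network_", assay, ".sif"))
    write_network(net, gml, "graphml")
    write_network(net, sif, "sif")
    files <- c(files, gml, sif)
    stages[[assay]] <- list(n_final = nrow(ds), n_mmps = nrow(mmps))
  }
  emit(summarize_table1(datasets, with_diversity = with_diversity),
       "table1.csv")
  emit(summarize_table2(mmps_list), "table2.csv")
  profiles <- drop_both_inactive(
    intersect_assays(datasets$agonist, datasets$antagonist))
  emit(profiles, "moa_profiles.csv")
  emit(dual_action(profiles), "dual_action.csv")
  if (nrow(profiles) >= 2L) {
    moa <- moa_mmp_pipeline(profiles, max_cuts = max_cuts, seed = seed)
    emit(moa$pairs, "moa_pairs.csv")
    emit(moa$summary, "table3.csv")
    stages$combined <- list(n_profiles = nrow(profiles),
                            n_moa_mmps = nrow(moa$pairs))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("moacliff")),
    seed = seed,
    max_cuts = max_cuts,
    timestamp = format(Sys.time(), tz = "UTC"),
    stage_counts = stages,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
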