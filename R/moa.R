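# Cross-assay mechanism-of-action (MOA) analysis: the curated agonist and
# antagonist datasets are intersected over their common compounds, each
# compound's pair of binary outcomes is reduced to a MOA label set
# ({agonist}, {antagonist} or {agonist, antagonist}), and MMPs generated
# over those compounds are classified by the set relation of the two label
# sets: equal -> same MOA, overlapping but unequal -> weak MOA-cliff,
# disjoint -> strong MOA-cliff.

MOA_LABELS <- c("agonist", "antagonist", "dual")

#' Intersect the curated agonist and antagonist datasets
#'
#' One MOA profile per compound present (with a binary outcome) in both
#' curated datasets. The label set is encoded as `"agonist"`,
#' `"antagonist"` or `"dual"`; compounds inactive in both assays carry an
#' empty label (`NA`) until [drop_both_inactive()].
#'
#' @param agonist,antagonist Curated `assay_tbl` datasets.
#' @return Tibble with `cid`, `smiles`, `agonist_outcome`,
#'   `antagonist_outcome`, `label_set`.
#' @export
intersect_assays <- function(agonist, antagonist) {
  ag <- tibble::as_tibble(agonist)[, c("cid", "smiles", "outcome")]
  an <- tibble::as_tibble(antagonist)[, c("cid", "outcome")]
  dplyr::inner_join(ag, an, by = "cid", suffix = c("_ag", "_an")) |>
    dplyr::transmute(
      cid = .data$cid, smiles = .data$smiles,
      agonist_outcome = .data$outcome_ag,
      antagonist_outcome = .data$outcome_an,
      label_set = moa_label(.data$agonist_outcome, .data$antagonist_outcome)
    )
}

#' @noRd
moa_label <- function(agonist_outcome, antagonist_outcome) {
  dplyr::case_when(
    agonist_outcome == "Active" & antagonist_outcome == "Active" ~ "dual",
    agonist_outcome == "Active" ~ "agonist",
    antagonist_outcome == "Active" ~ "antagonist",
    TRUE ~ NA_character_
  )
}

#' Drop compounds inactive in both assays
#'
#' @param profiles Output of [intersect_assays()].
#' @return Profiles with a non-empty MOA label set.
#' @export
drop_both_inactive <- function(profiles) {
  dplyr::filter(profiles, !is.na(.data$label_set))
}

#' Dual-action compounds
#'
#' Compounds reported active in both the agonist and the antagonist screen.
#'
#' @param profiles MOA profiles (after [drop_both_inactive()]).
#' @return The dual-action subset of `profiles`.
#' @export
dual_action <- function(profiles) {
  dplyr::filter(profiles, .data$label_set == "dual")
}

#' Classify an MMP by its members' MOA label sets
#'
#' Equal label sets give `same_moa`; disjoint singleton sets (a pure
#' agonist paired with a pure antagonist) give `strong_cliff`; overlapping
#' but unequal sets (a dual-action compound paired with a single-MOA one)
#' give `weak_cliff`. Symmetric in the pair.
#'
#' @param left,right Character vectors over `"agonist"`, `"antagonist"`,
#'   `"dual"`.
#' @return Character vector over `same_moa`, `weak_cliff`, `strong_cliff`.
#' @export
classify_moa <- function(left, right) {
  stopifnot(all(left %in% MOA_LABELS), all(right %in% MOA_LABELS))
  dplyr::case_when(
    left == right ~ "same_moa",
    left == "dual" | right == "dual" ~ "weak_cliff",
    TRUE ~ "strong_cliff"
  )
}

#' MMP and MOA-cliff analysis of the combined dataset
#'
#' Runs the MMP machinery (same size restrictions and deduplication as the
#' single-assay analysis) over the profiled common compounds, classifies
#' each MMP by the MOA label sets of its members, and tabulates counts per
#' category and outcome pattern.
#'
#' @param profiles MOA profiles after [drop_both_inactive()].
#' @param max_cuts,core_ratio,max_frag_heavy,max_delta,seed Passed to the
#'   MMP stages.
#' @return An object of class `moa_result`: list with `pairs` (one row per
#'   MMP with `moa_category`) and `summary` (category x outcome-pattern
#'   counts). See [tidy.moa_result()] and [glance.moa_result()].
#' @export
moa_mmp_pipeline <- function(profiles, max_cuts = 1L, core_ratio = 2,
                             max_frag_heavy = 13L, max_delta = 8L,
                             seed = 1L) {
  stopifnot(!anyNA(profiles$label_set))
  mmps <- enumerate_fragmentations(profiles, max_cuts = max_cuts) |>
    index_pairs() |>
    size_filter(core_ratio = core_ratio, max_frag_heavy = max_frag_heavy,
                max_delta = max_delta) |>
    deduplicate_pairs(seed = seed)
  lut <- profiles[, c("cid", "agonist_outcome", "antagonist_outcome",
                      "label_set")]
  pairs <- mmps |>
    dplyr::left_join(
      stats::setNames(lut, paste0(names(lut), "_left")),
      by = c(cid_left = "cid_left")
    ) |>
    dplyr::left_join(
      stats::setNames(lut, paste0(names(lut), "_right")),
      by = c(cid_right = "cid_right")
    ) |>
    dplyr::mutate(moa_category = classify_moa(.data$label_set_left,
                                              .data$label_set_right))
  summary <- pairs |>
    dplyr::count(
      .data$moa_category,
      pattern = paste(.data$agonist_outcome_left,
                      .data$antagonist_outcome_left,
                      .data$agonist_outcome_right,
                      .data$antagonist_outcome_right, sep = "/"),
      name = "n_mmps"
    ) |>
    dplyr::arrange(factor(.data$moa_category,
                          c("same_moa", "weak_cliff", "strong_cliff")))
  structure(list(pairs = pairs, summary = summary), class = "moa_result")
}

#' @export
print.moa_result <- function(x, ...) {
  counts <- table(factor(x$pairs$moa_category,
                         c("same_moa", "weak_cliff", "strong_cliff")))
  cat(sprintf(
    "<moa_result: %d MMPs; %d same MOA, %d weak MOA-cliffs, %d strong MOA-cliffs>\n",
    nrow(x$pairs), counts[["same_moa"]], counts[["weak_cliff"]],
    counts[["strong_cliff"]]))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Tidy a MOA analysis result
#'
#' @param x A `moa_result`.
#' @param ... Unused.
#' @return The per-MMP table with member profiles and `moa_category`.
#' @export
tidy.moa_result <- function(x, ...) x$pairs

#' One-row overview of a MOA analysis result
#'
#' @param x A `moa_result`.
#' @param ... Unused.
#' @return One-row tibble with total and per-category MMP counts.
#' @export
glance.moa_result <- function(x, ...) {
  counts <- table(factor(x$pairs$moa_category,
                         c("same_moa", "weak_cliff", "strong_cliff")))
  tibble::tibble(
    n_mmps = nrow(x$pairs),
    n_same_moa = as.integer(counts[["same_moa"]]),
    n_weak_cliff = as.integer(counts[["weak_cliff"]]),
    n_strong_cliff = as.integer(counts[["strong_cliff"]])
  )
}
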