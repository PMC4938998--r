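# Bemis-Murcko scaffolds and cyclic skeletons (CSKs), and the frequency,
# ring-count, exclusivity and potency statistics computed over them.
#
# The scaffold of a molecule keeps all ring systems, the linker atoms and
# bonds connecting them, and any atom attached to a ring or linker atom by
# a bond of order two or higher (so an exocyclic carbonyl oxygen stays).
# The CSK then replaces every atom by carbon and every bond by a single
# bond, so that topologically equivalent scaffolds collapse to one key.
# Scaffold identity is canonical-string equality; stereochemistry is not
# part of a scaffold key.

#' Bemis-Murcko scaffold of each molecule
#'
#' @param smiles Character vector of SMILES; every molecule must contain at
#'   least one ring (ringless compounds are filtered upstream by
#'   [remove_ringless()]).
#' @return Character vector of canonical scaffold SMILES.
#' @examples
#' \dontrun{
#' bm_scaffold("Cc1ccccc1")  # toluene -> benzene
#' }
#' @export
bm_scaffold <- function(smiles) {
  mols <- mols_from_smiles(smiles)
  bad <- vapply(mols, is.null, logical(1)) & !is.na(smiles)
  if (any(bad)) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[bad], 5), collapse = ", "), call. = FALSE)
  }
  sc <- lapply(mols, function(m) if (is.null(m)) NULL else mol_bm_scaffold(m))
  ringless <- vapply(sc, is.null, logical(1)) & !vapply(mols, is.null, logical(1))
  if (any(ringless)) {
    stop("molecule(s) without rings have no scaffold: ",
         paste(utils::head(smiles[ringless], 5), collapse = ", "),
         call. = FALSE)
  }
  mols_to_cansmi(sc)
}

#' Cyclic skeleton (CSK) of each scaffold
#'
#' Converts every atom to carbon and every bond order to one, removing
#' aromaticity, then canonicalizes. Idempotent; two topologically identical
#' scaffolds map to the same CSK.
#'
#' @param scaffold Character vector of scaffold SMILES.
#' @return Character vector of canonical CSK SMILES.
#' @examples
#' \dontrun{
#' csk_of(c("c1ccncc1", "c1ccccc1"))  # both give cyclohexane
#' }
#' @export
csk_of <- function(scaffold) {
  mols <- mols_from_smiles(scaffold)
  bad <- vapply(mols, is.null, logical(1)) & !is.na(scaffold)
  if (any(bad)) {
    stop("unparseable SMILES: ",
         paste(utils::head(scaffold[bad], 5), collapse = ", "), call. = FALSE)
  }
  mols_to_cansmi(lapply(mols, function(m) if (is.null(m)) NULL else mol_csk(m)))
}

#' Ring count (SSSR cardinality) of each molecule
#'
#' @param smiles Character vector of SMILES.
#' @return Integer vector of smallest-set-of-smallest-rings sizes.
#' @export
ring_count <- function(smiles) {
  mols <- mols_from_smiles(smiles)
  vapply(mols, function(m) {
    if (is.null(m)) NA_integer_ else mol_ring_count(m)
  }, integer(1))
}

#' Assign scaffold, CSK and ring count to every compound
#'
#' @param ds A curated `assay_tbl` (or any tibble with `cid`, `smiles` and
#'   `outcome` columns).
#' @return Tibble with `cid`, `outcome`, `scaffold`, `csk`, `n_rings`.
#' @export
assign_scaffolds <- function(ds) {
  usm <- unique(ds$smiles)
  sc <- bm_scaffold(usm)
  lut <- tibble::tibble(smiles = usm, scaffold = sc)
  usc <- unique(sc)
  lut2 <- tibble::tibble(scaffold = usc, csk = csk_of(usc),
                         n_rings = ring_count(usc))
  ds |>
    tibble::as_tibble() |>
    dplyr::select("cid", "smiles", "outcome") |>
    dplyr::left_join(lut, by = "smiles") |>
    dplyr::left_join(lut2, by = "scaffold") |>
    dplyr::select("cid", "outcome", "scaffold", "csk", "n_rings")
}

#' Summarize the scaffold population of a dataset
#'
#' Computes per-scaffold compound counts, per-CSK scaffold counts, the
#' fraction of singleton scaffolds (scaffolds covering exactly one
#' compound), the ring-count histogram, and the exclusivity partition:
#' scaffolds covering only active compounds, only inactive compounds, or
#' both (overlap).
#'
#' @param assignments Output of [assign_scaffolds()] (columns `cid`,
#'   `outcome`, `scaffold`, `csk`, `n_rings`).
#' @return A `scaffold_summary` object; see [tidy.scaffold_summary()] and
#'   [glance.scaffold_summary()].
#' @export
summarize_scaffolds <- function(assignments) {
  per_scaffold <- assignments |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::summarise(
      csk = .data$csk[1],
      n_rings = .data$n_rings[1],
      n_compounds = dplyr::n(),
      n_active = sum(.data$outcome == "Active"),
      n_inactive = sum(.data$outcome == "Inactive"),
      .groups = "drop"
    ) |>
    dplyr::mutate(exclusivity = dplyr::case_when(
      .data$n_active > 0L & .data$n_inactive == 0L ~ "exclusive_active",
      .data$n_active == 0L & .data$n_inactive > 0L ~ "exclusive_inactive",
      TRUE ~ "overlap"
    ))
  per_csk <- per_scaffold |>
    dplyr::count(.data$csk, name = "n_scaffolds")
  ring_hist <- per_scaffold |>
    dplyr::count(.data$n_rings, .data$exclusivity, name = "n_scaffolds")
  structure(
    list(
      per_scaffold = per_scaffold,
      per_csk = per_csk,
      ring_histogram = ring_hist,
      n_compounds = nrow(assignments),
      n_scaffolds = nrow(per_scaffold),
      n_csk = nrow(per_csk),
      singleton_fraction = mean(per_scaffold$n_compounds == 1L),
      exclusive_active = per_scaffold$scaffold[
        per_scaffold$exclusivity == "exclusive_active"],
      exclusive_inactive = per_scaffold$scaffold[
        per_scaffold$exclusivity == "exclusive_inactive"],
      overlap = per_scaffold$scaffold[per_scaffold$exclusivity == "overlap"]
    ),
    class = "scaffold_summary"
  )
}

#' @export
print.scaffold_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<scaffold_summary: %d compounds, %d scaffolds, %d CSKs>\n",
    "  singleton scaffolds: %.0f%%\n",
    "  exclusivity: %d active-only / %d overlap / %d inactive-only\n"),
    x$n_compounds, x$n_scaffolds, x$n_csk, 100 * x$singleton_fraction,
    length(x$exclusive_active), length(x$overlap),
    length(x$exclusive_inactive)))
  invisible(x)
}

#' Tidy a scaffold summary
#'
#' @param x A `scaffold_summary`.
#' @param ... Unused.
#' @return The per-scaffold table: scaffold, CSK, ring count, compound
#'   counts by outcome and exclusivity class.
#' @export
tidy.scaffold_summary <- function(x, ...) x$per_scaffold

#' One-row overview of a scaffold summary
#'
#' @param x A `scaffold_summary`.
#' @param ... Unused.
#' @return One-row tibble with the headline counts.
#' @export
glance.scaffold_summary <- function(x, ...) {
  tibble::tibble(
    n_compounds = x$n_compounds,
    n_scaffolds = x$n_scaffolds,
    n_csk = x$n_csk,
    singleton_fraction = x$singleton_fraction,
    n_exclusive_active = length(x$exclusive_active),
    n_overlap = length(x$overlap),
    n_exclusive_inactive = length(x$exclusive_inactive)
  )
}

#' Potency profile of the exclusively-active scaffolds
#'
#' For each scaffold covering only active compounds, reports the number of
#' compounds with an aggregated potency and the min/max pIC50 over them.
#' Scaffolds whose compounds were all dropped by the potency aggregation
#' rule (or never had a reading) are excluded.
#'
#' @param summary A `scaffold_summary`.
#' @param assignments The [assign_scaffolds()] table used to build it.
#' @param potencies Output of [aggregate_potencies()] (`cid`, `pic50`).
#' @return Tibble with `scaffold`, `n_compounds`, `pic50_min`, `pic50_max`.
#' @export
exclusive_potency_profile <- function(summary, assignments, potencies) {
  hits <- assignments |>
    dplyr::filter(.data$scaffold %in% summary$exclusive_active) |>
    dplyr::inner_join(potencies, by = "cid")
  if (nrow(hits) == 0L) {
    return(tibble::tibble(scaffold = character(), n_compounds = integer(),
                          pic50_min = numeric(), pic50_max = numeric()))
  }
  hits |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::summarise(
      n_compounds = dplyr::n(),
      pic50_min = min(.data$pic50),
      pic50_max = max(.data$pic50),
      .groups = "drop"
    )
}
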