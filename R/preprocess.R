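# Six-step curation of a raw bioassay dataset, with a unique-compound audit
# trail, plus the pIC50 aggregation rules applied to active compounds.

append_audit <- function(before, after, stage) {
  au <- audit_trail(before)
  n_before <- dplyr::n_distinct(before$cid)
  n_after <- dplyr::n_distinct(after$cid)
  row <- tibble::tibble(
    stage = stage, n_before = n_before,
    n_removed = n_before - n_after, n_after = n_after,
    n_records_after = nrow(after)
  )
  as_assay_tbl(after, audit = dplyr::bind_rows(au, row),
               source_assay = attr(before, "source_assay"))
}

PIPELINE_STAGES <- c("missing_readouts", "collapse_redundant",
                     "drop_discrepant", "binary_outcomes",
                     "remove_mixtures", "remove_ringless")

#' Curation step 1: drop records with missing readouts
#'
#' Removes every record whose outcome is `Missing` and appends an audit row.
#'
#' @param ds An `assay_tbl`.
#' @return The filtered `assay_tbl`.
#' @export
filter_missing_readouts <- function(ds) {
  append_audit(ds, dplyr::filter(ds, .data$outcome != "Missing"),
               "missing_readouts")
}

#' Curation step 2: collapse redundant substance records
#'
#' For each compound whose records all share one outcome, exactly one
#' record is kept, with the potency lists concatenated. The unique-compound
#' count is unchanged; compounds with discrepant outcomes are left for the
#' next step.
#'
#' @param ds An `assay_tbl`.
#' @return The collapsed `assay_tbl`.
#' @export
collapse_redundant <- function(ds) {
  out <- ds |>
    dplyr::group_by(.data$cid) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) > 1L && dplyr::n_distinct(g$outcome) == 1L) {
        g$potencies[[1]] <- purrr::flatten_dbl(g$potencies)
        g <- g[1, , drop = FALSE]
      }
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(names(ds)))
  append_audit(ds, out, "collapse_redundant")
}

#' Curation step 3: drop compounds with discrepant outcomes
#'
#' Removes every compound (all of its records) reported with two or more
#' distinct outcomes across substances.
#'
#' @param ds An `assay_tbl`.
#' @return The filtered `assay_tbl`.
#' @export
drop_discrepant <- function(ds) {
  bad <- ds |>
    dplyr::count(.data$cid, .data$outcome) |>
    dplyr::count(.data$cid) |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::pull(.data$cid)
  append_audit(ds, dplyr::filter(ds, !(.data$cid %in% bad)), "drop_discrepant")
}

#' Curation step 4: keep binary outcomes only
#'
#' Retains only compounds annotated `Active` or `Inactive`.
#'
#' @param ds An `assay_tbl`.
#' @return The filtered `assay_tbl`.
#' @export
keep_binary_outcomes <- function(ds) {
  append_audit(ds, dplyr::filter(ds, .data$outcome %in% c("Active", "Inactive")),
               "binary_outcomes")
}

#' Curation step 5: remove mixtures
#'
#' Removes compounds whose structure has more than one covalently connected
#' component (dot-disconnected SMILES). Unparseable structures are removed
#' here too, with a warning, since HTS exports routinely contain bad
#' structure fields.
#'
#' @param ds An `assay_tbl`.
#' @return The filtered `assay_tbl`.
#' @export
remove_mixtures <- function(ds) {
  usm <- unique(ds$smiles)
  mols <- mols_from_smiles(usm)
  bad_parse <- vapply(mols, is.null, logical(1))
  if (any(bad_parse)) {
    warning(sum(bad_parse), " unparseable structure(s) removed at the ",
            "mixture stage", call. = FALSE)
  }
  ncomp <- vapply(mols, function(m) {
    if (is.null(m)) NA_integer_ else mol_n_components(m)
  }, integer(1))
  keep_smiles <- usm[!bad_parse & ncomp == 1L]
  append_audit(ds, dplyr::filter(ds, .data$smiles %in% keep_smiles),
               "remove_mixtures")
}

#' Curation step 6: remove ringless compounds
#'
#' Removes compounds whose molecular graph contains no ring.
#'
#' @param ds An `assay_tbl`.
#' @return The filtered `assay_tbl`.
#' @export
remove_ringless <- function(ds) {
  usm <- unique(ds$smiles)
  mols <- mols_from_smiles(usm)
  nring <- vapply(mols, function(m) {
    if (is.null(m)) 0L else mol_ring_count(m)
  }, integer(1))
  keep_smiles <- usm[nring >= 1L]
  append_audit(ds, dplyr::filter(ds, .data$smiles %in% keep_smiles),
               "remove_ringless")
}

#' Run the full six-step curation pipeline
#'
#' Applies, in order: missing-readout removal, redundant-record collapse,
#' discrepant-compound removal, binary-outcome restriction, mixture removal
#' and ringless-compound removal. The result carries a six-row audit trail
#' (unique compounds per stage); see [audit_trail()].
#'
#' @param ds A raw `assay_tbl` as returned by [read_bioassay_table()].
#' @return The curated `assay_tbl` with one record per compound.
#' @export
run_pipeline <- function(ds) {
  ds |>
    filter_missing_readouts() |>
    collapse_redundant() |>
    drop_discrepant() |>
    keep_binary_outcomes() |>
    remove_mixtures() |>
    remove_ringless()
}

#' Convert IC50 in micromolar to pIC50 (molar)
#'
#' `pIC50 = -log10(IC50[M]) = 6 - log10(IC50[uM])`; 1 uM gives 6.0.
#'
#' @param ic50_um Numeric vector, strictly positive, in micromolar.
#' @return Numeric vector of pIC50 values.
#' @export
pic50_from_um <- function(ic50_um) {
  if (any(!is.na(ic50_um) & ic50_um <= 0)) {
    stop("IC50 values must be strictly positive", call. = FALSE)
  }
  6 - log10(ic50_um)
}

#' Aggregate multiple potency readings for one compound
#'
#' Each IC50 (micromolar) is converted to pIC50 (molar). If the pIC50
#' spread is at most one log order the mean is returned; if the readings
#' disagree by more than one log order the compound is flagged as dropped.
#' A single reading is returned as is. The rule is permutation-invariant.
#'
#' @param values Numeric vector of IC50 values in micromolar.
#' @return One-row tibble with `pic50`, `n_merged`, `dropped`.
#' @examples
#' aggregate_potency(1.0)           # pIC50 6.0
#' aggregate_potency(c(10, 0.1))    # spread 2 log orders: dropped
#' @export
aggregate_potency <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    stop("no potency values to aggregate", call. = FALSE)
  }
  p <- pic50_from_um(values)
  spread <- max(p) - min(p)
  tibble::tibble(
    pic50 = if (spread <= 1) mean(p) else NA_real_,
    n_merged = length(p),
    dropped = spread > 1
  )
}

#' Aggregate potencies across the active compounds of a curated dataset
#'
#' Applies [aggregate_potency()] to every `Active` compound that has at
#' least one potency reading. Compounds whose readings disagree by more
#' than one log order are excluded; their identifiers are attached as the
#' `dropped_cids` attribute.
#'
#' @param ds A curated `assay_tbl`.
#' @return Tibble with `cid`, `pic50`, `n_merged`, one row per retained
#'   active compound.
#' @export
aggregate_potencies <- function(ds) {
  act <- dplyr::filter(ds, .data$outcome == "Active",
                       purrr::map_int(.data$potencies, length) > 0L)
  res <- act |>
    dplyr::mutate(agg = purrr::map(.data$potencies, aggregate_potency)) |>
    tidyr::unnest("agg") |>
    dplyr::select("cid", "pic50", "n_merged", "dropped")
  out <- dplyr::select(dplyr::filter(res, !.data$dropped), -"dropped")
  attr(out, "dropped_cids") <- res$cid[res$dropped]
  out
}
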