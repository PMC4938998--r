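#' Column mapping for a bioassay result table
#'
#' Describes which columns of a PubChem-BioAssay-style CSV/TSV export hold
#' the substance identifier, compound identifier, structure, activity
#' outcome and (optionally) potency. Mappings can also be loaded from a
#' YAML file with a top-level `columns:` block via [read_dialect()].
#'
#' @param sid,cid,smiles,outcome Column names (required).
#' @param potency Column name holding an IC50 in micromolar, or `NULL` if
#'   the table has no potency column.
#' @return A named list of class `bioassay_dialect`.
#' @examples
#' bioassay_dialect(sid = "SID", cid = "CID", smiles = "SMILES",
#'                  outcome = "Outcome", potency = "IC50")
#' @export
bioassay_dialect <- function(sid = "PUBCHEM_SID", cid = "PUBCHEM_CID",
                             smiles = "PUBCHEM_EXT_DATASOURCE_SMILES",
                             outcome = "PUBCHEM_ACTIVITY_OUTCOME",
                             potency = NULL) {
  d <- list(sid = sid, cid = cid, smiles = smiles, outcome = outcome,
            potency = potency)
  for (f in c("sid", "cid", "smiles", "outcome")) {
    if (!is.character(d[[f]]) || length(d[[f]]) != 1L || !nzchar(d[[f]])) {
      stop("dialect field '", f, "' must be a single column name", call. = FALSE)
    }
  }
  structure(d, class = "bioassay_dialect")
}

#' Read a column-mapping dialect from a YAML file
#'
#' @param path Path to a YAML file with a `columns:` mapping naming the
#'   `sid`, `cid`, `smiles`, `outcome` and optionally `potency` columns.
#' @return A `bioassay_dialect`.
#' @export
read_dialect <- function(path) {
  y <- yaml::read_yaml(path)
  cols <- y$columns %||% y
  bioassay_dialect(
    sid = cols$sid, cid = cols$cid, smiles = cols$smiles,
    outcome = cols$outcome, potency = cols$potency
  )
}

OUTCOME_LEVELS <- c("Active", "Inactive", "Other", "Missing")

#' Normalize free-text outcome annotations
#'
#' Case-insensitive mapping to the four-level vocabulary: `Active` and
#' `Inactive` map to themselves, an absent value maps to `Missing`, and any
#' other annotation (e.g. "Inconclusive") maps to `Other`.
#'
#' @param x Character vector of raw outcome annotations.
#' @return Character vector over `Active`, `Inactive`, `Other`, `Missing`.
#' @export
normalize_outcome <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  dplyr::case_when(
    is.na(x) | lx == "" ~ "Missing",
    lx == "active" ~ "Active",
    lx == "inactive" ~ "Inactive",
    TRUE ~ "Other"
  )
}

#' Construct an assay dataset from a records table
#'
#' @param records Tibble with columns `sid`, `cid`, `smiles`, `outcome`,
#'   `potencies` (list of numeric) and `source_assay`.
#' @param audit Audit-trail tibble (stage, n_before, n_removed, n_after).
#' @param source_assay `"agonist"` or `"antagonist"`.
#' @return An `assay_tbl` (a tibble with an audit-trail attribute).
#' @export
as_assay_tbl <- function(records,
                         audit = empty_audit(),
                         source_assay = records$source_assay[1] %||% NA_character_) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("sid", "cid", "smiles", "outcome", "potencies") %in%
                  names(records)))
  bad_pot <- purrr::map_lgl(records$potencies, ~ any(!is.na(.x) & .x <= 0))
  if (any(bad_pot)) {
    stop("potencies must be strictly positive (IC50 in micromolar)",
         call. = FALSE)
  }
  structure(records,
            audit = audit,
            source_assay = source_assay,
            class = c("assay_tbl", class(tibble::tibble())))
}

empty_audit <- function() {
  tibble::tibble(stage = character(), n_before = integer(),
                 n_removed = integer(), n_after = integer(),
                 n_records_after = integer())
}

#' Per-stage curation audit trail of an assay dataset
#'
#' @param ds An `assay_tbl`.
#' @return Tibble with one row per curation stage: `stage`, `n_before`,
#'   `n_removed`, `n_after` (all in unique compounds), plus
#'   `n_records_after` (substance records).
#' @export
audit_trail <- function(ds) {
  attr(ds, "audit") %||% empty_audit()
}

#' @export
print.assay_tbl <- function(x, ...) {
  cat(sprintf("<assay_tbl: %s assay, %d records, %d unique compounds>\n",
              attr(x, "source_assay") %||% "?", nrow(x),
              dplyr::n_distinct(x$cid)))
  NextMethod()
  au <- audit_trail(x)
  if (nrow(au)) {
    cat("Audit trail (unique compounds):\n")
    print(as.data.frame(au), row.names = FALSE)
  }
  invisible(x)
}

#' Read a bioassay result table
#'
#' Reads a PubChem-BioAssay-style CSV/TSV export into an [as_assay_tbl()]
#' dataset: one record per row, outcomes normalized with
#' [normalize_outcome()], potencies parsed as IC50 in micromolar. The
#' reader is non-destructive: duplicate rows, discrepant outcomes and bad
#' structures are kept for the curation pipeline to handle.
#'
#' @param path Path to a CSV (or TSV, by extension) file.
#' @param dialect A [bioassay_dialect()] mapping the columns.
#' @param source_assay Label for the assay arm, `"agonist"` or
#'   `"antagonist"`.
#' @return An `assay_tbl`. Unparseable potency cells yield an empty potency
#'   list with a warning; an empty file yields an empty dataset.
#' @export
read_bioassay_table <- function(path, dialect = bioassay_dialect(),
                                source_assay = "agonist") {
  stopifnot(file.exists(path))
  reader <- if (grepl("\\.tsv$|\\.txt$", path)) readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  needed <- c(dialect$sid, dialect$cid, dialect$smiles, dialect$outcome)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("input table lacks mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pot <- if (!is.null(dialect$potency) && dialect$potency %in% names(raw)) {
    txt <- raw[[dialect$potency]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- !is.na(txt) & nzchar(trimws(txt)) & is.na(val)
    if (any(bad)) {
      warning(sum(bad), " unparseable potency value(s) dropped", call. = FALSE)
    }
    purrr::map(val, ~ if (is.na(.x)) numeric() else .x)
  } else {
    rep(list(numeric()), nrow(raw))
  }
  rec <- tibble::tibble(
    sid = as.character(raw[[dialect$sid]]),
    cid = as.character(raw[[dialect$cid]]),
    smiles = as.character(raw[[dialect$smiles]]),
    outcome = normalize_outcome(raw[[dialect$outcome]]),
    potencies = pot,
    source_assay = source_assay
  )
  as_assay_tbl(rec, source_assay = source_assay)
}

#' Canonicalize SMILES strings
#'
#' Converts each structure to its canonical SMILES form (OpenBabel
#' canonical order), so that identical molecules written differently
#' compare equal as strings. Canonicalization is idempotent.
#'
#' @param smiles Character vector of SMILES.
#' @param strict If `TRUE` (default) an unparseable input is an error
#'   naming the offending string; if `FALSE` it yields `NA`.
#' @return Character vector of canonical SMILES.
#' @examples
#' \dontrun{
#' canonical_smiles(c("C1=CC=CC=C1", "c1ccccc1")) # identical output
#' }
#' @export
canonical_smiles <- function(smiles, strict = TRUE) {
  out <- smiles_to_cansmi(smiles)
  if (strict && anyNA(out[!is.na(smiles)])) {
    bad <- smiles[!is.na(smiles) & is.na(out)]
    stop("unparseable SMILES: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write a table to CSV/TSV
#'
#' Writes with a header row, UTF-8. List columns (e.g. potency lists) are
#' flattened to `;`-separated strings so the file round-trips through
#' [readr::read_csv()].
#'
#' @param rows A data frame.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(!is.null(rows))
  flat <- dplyr::mutate(
    tibble::as_tibble(rows),
    dplyr::across(dplyr::where(is.list),
                  ~ purrr::map_chr(.x, paste, collapse = ";"))
  )
  if (grepl("\\.tsv$", path)) readr::write_tsv(flat, path)
  else readr::write_csv(flat, path)
  invisible(path)
}

#' @importFrom rlang %||%
NULL
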