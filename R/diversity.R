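# Binary substructure-path fingerprints and the diversity index (DI) of a
# compound set: the mean pairwise Tanimoto distance (1 - similarity), with
# a nearest-neighbour variant available. The fingerprint dialect is
# OpenBabel FP2 (1024-bit hashed linear fragments up to 7 atoms); DI values
# are internally consistent per dialect.

#' Binary fingerprints for a set of molecules
#'
#' @param smiles Character vector of SMILES.
#' @param dialect Fingerprint name understood by OpenBabel (default
#'   `"FP2"`, a 1024-bit path-based substructure fingerprint).
#' @return Logical matrix, one row per molecule (rownames = input SMILES),
#'   with a `dialect` attribute. Identical molecules give identical rows.
#' @export
fingerprint <- function(smiles, dialect = "FP2") {
  stopifnot(length(smiles) > 0L)
  if (anyNA(smiles) || !all(nzchar(trimws(smiles)))) {
    stop("fingerprint() requires non-empty SMILES", call. = FALSE)
  }
  # parse check first, for a clean error naming the offender
  can <- smiles_to_cansmi(smiles)
  if (anyNA(can)) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[is.na(can)], 5), collapse = ", "),
         call. = FALSE)
  }
  src <- paste(paste(smiles, paste0("m", seq_along(smiles))), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", src, identity)
  fp <- ChemmineOB::fingerprint_OB(mols, dialect)
  fp <- fp > 0
  rownames(fp) <- smiles
  attr(fp, "dialect") <- dialect
  fp
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`; symmetric, 1 for identical non-empty
#' fingerprints. Two all-zero fingerprints compare as 0 with a warning.
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) {
    stop("fingerprint lengths differ (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  denom <- sum(a | b)
  if (denom == 0L) {
    warning("both fingerprints are empty; Tanimoto defined as 0",
            call. = FALSE)
    return(0)
  }
  sum(a & b) / denom
}

#' Diversity index of a compound set
#'
#' The default (`method = "pairwise"`) is the mean of `1 - Tanimoto` over
#' all unordered fingerprint pairs: 0 for a homogeneous set, 1 for
#' pairwise-disjoint fingerprints, invariant to input order. The
#' `"nearest"` variant averages, over compounds, one minus the maximal
#' similarity to any other member.
#'
#' @param fps Logical fingerprint matrix from [fingerprint()] (rows =
#'   molecules), with at least two rows.
#' @param method `"pairwise"` (default) or `"nearest"`.
#' @return A number in `[0, 1]`.
#' @export
diversity_index <- function(fps, method = c("pairwise", "nearest")) {
  method <- match.arg(method)
  if (is.null(dim(fps)) || nrow(fps) < 2L) {
    stop("diversity_index needs at least two fingerprints", call. = FALSE)
  }
  m <- matrix(as.numeric(fps), nrow = nrow(fps))
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  n <- nrow(m)
  if (method == "pairwise") {
    mean(1 - sim[upper.tri(sim)])
  } else {
    diag(sim) <- -Inf
    mean(1 - apply(sim, 1, max))
  }
}
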