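# Size-restricted matched molecular pairs (MMPs) by fragment-and-index:
# every acyclic single bond between heavy atoms is cut once (single-cut
# mode; a double-cut mode exchanges inner linkers), compounds are indexed
# by the canonical invariant core, and each unordered compound pair sharing
# a core with different exchanged fragments yields one candidate pair.
# Candidates then pass the size restrictions, are reduced to one MMP per
# compound pair (smallest heavy-atom deviation, seeded random tie-break),
# and are classified by the binary outcomes of their members.

#' Enumerate fragmentations of a compound set
#'
#' Cuts every acyclic single bond between two heavy atoms once. For single
#' cuts the invariant core is the larger side (on a tie both orientations
#' are emitted); for double cuts every unordered pair of such bonds yields
#' a two-attachment core and an inner linker fragment, with numbered
#' attachment labels assigned so the core string is lexicographically
#' minimal. Attachment points count zero heavy atoms.
#'
#' @param compounds Data frame with `cid` and `smiles` columns, or a bare
#'   character vector of SMILES (then used as their own identifiers).
#' @param max_cuts 1 (default) or 2.
#' @return Tibble with `cid`, `core`, `fragment`, `core_heavy`,
#'   `frag_heavy`, `n_cuts`; zero rows for molecules with no cuttable bond.
#' @export
enumerate_fragmentations <- function(compounds, max_cuts = 1L) {
  stopifnot(max_cuts %in% c(1L, 2L))
  if (is.character(compounds)) {
    compounds <- tibble::tibble(cid = compounds, smiles = compounds)
  }
  compounds <- dplyr::distinct(
    tibble::as_tibble(compounds)[, c("cid", "smiles")]
  )
  mols <- mols_from_smiles(compounds$smiles)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    stop("unparseable SMILES: ",
         paste(utils::head(compounds$smiles[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  # collect every part first, canonicalize in one batch
  parts <- list()   # mol objects
  meta <- list()    # row skeletons with indices into `parts`
  push <- function(m) {
    parts[[length(parts) + 1L]] <<- m
    length(parts)
  }
  dc_id <- 0L
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    cid <- compounds$cid[i]
    cuts <- mol_cut_bonds(mol)
    for (b in cuts) {
      sides <- mol_split_bond(mol, b)
      h1 <- mol_n_heavy(sides[[1]])
      h2 <- mol_n_heavy(sides[[2]])
      orient <- if (h1 > h2) list(c(1L, 2L)) else if (h2 > h1) {
        list(c(2L, 1L))
      } else {
        list(c(1L, 2L), c(2L, 1L))
      }
      for (o in orient) {
        meta[[length(meta) + 1L]] <- list(
          cid = cid, n_cuts = 1L,
          core_i = push(sides[[o[1]]]), frag_i = push(sides[[o[2]]]),
          core_heavy = c(h1, h2)[o[1]], frag_heavy = c(h1, h2)[o[2]],
          dc = NA_integer_
        )
      }
    }
    if (max_cuts == 2L && length(cuts) >= 2L) {
      cmb <- utils::combn(cuts, 2L)
      for (k in seq_len(ncol(cmb))) {
        dc <- double_cut(mol, cmb[1L, k], cmb[2L, k])
        if (is.null(dc)) next
        dc_id <- dc_id + 1L
        for (lab in 1:2) {
          meta[[length(meta) + 1L]] <- list(
            cid = cid, n_cuts = 2L,
            core_i = push(dc$core[[lab]]), frag_i = push(dc$frag[[lab]]),
            core_heavy = dc$core_heavy, frag_heavy = dc$frag_heavy,
            dc = dc_id
          )
        }
      }
    }
  }
  if (!length(meta)) {
    return(tibble::tibble(cid = character(), core = character(),
                          fragment = character(), core_heavy = integer(),
                          frag_heavy = integer(), n_cuts = integer()))
  }
  smi <- mols_to_cansmi(parts)
  out <- dplyr::bind_rows(lapply(meta, tibble::as_tibble))
  out$core <- smi[out$core_i]
  out$fragment <- smi[out$frag_i]
  # double-cut label symmetry: of the two labellings of one cut pair, keep
  # the one whose core string is lexicographically smaller
  single <- dplyr::filter(out, is.na(.data$dc))
  dbl <- out |>
    dplyr::filter(!is.na(.data$dc)) |>
    dplyr::group_by(.data$dc) |>
    dplyr::arrange(.data$core, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  dplyr::bind_rows(single, dbl) |>
    dplyr::select("cid", "core", "fragment", "core_heavy", "frag_heavy",
                  "n_cuts") |>
    dplyr::distinct()
}

# Split at two acyclic bonds: core = the two outer parts (labelled [1*],
# [2*]), fragment = the inner part carrying both labels. Returns both label
# assignments; NULL if the cut is degenerate.
#' @noRd
double_cut <- function(mol, b1, b2) {
  ends1 <- c(mol$bonds$a1[b1], mol$bonds$a2[b1])
  ends2 <- c(mol$bonds$a1[b2], mol$bonds$a2[b2])
  m2 <- new_mol(mol$elem, mol$bonds[-c(b1, b2), , drop = FALSE],
                mol$chg, mol$iso, mol$title)
  comp <- igraph::components(mol_igraph(m2))$membership
  mid <- intersect(comp[ends1], comp[ends2])
  if (length(mid) != 1L) return(NULL)
  at1 <- ends1[comp[ends1] == mid]
  at2 <- ends2[comp[ends2] == mid]
  out1 <- ends1[comp[ends1] != mid]
  out2 <- ends2[comp[ends2] != mid]
  if (!length(at1) || !length(at2) || !length(out1) || !length(out2)) {
    return(NULL)
  }
  mid_atoms <- which(comp == mid)
  build <- function(l1, l2) {
    frag <- mol_subset(m2, mid_atoms)
    frag <- add_dummy(frag, match(at1, sort(mid_atoms)), l1)
    frag <- add_dummy(frag, match(at2, sort(mid_atoms)), l2)
    outer_atoms <- sort(c(which(comp == comp[out1]), which(comp == comp[out2])))
    core <- mol_subset(m2, outer_atoms)
    core <- add_dummy(core, match(out1, outer_atoms), l1)
    core <- add_dummy(core, match(out2, outer_atoms), l2)
    list(core = core, frag = frag)
  }
  a <- build(1L, 2L)
  b <- build(2L, 1L)
  list(
    core = list(a$core, b$core),
    frag = list(a$frag, b$frag),
    core_heavy = mol_n_heavy(a$core),
    frag_heavy = mol_n_heavy(a$frag)
  )
}

#' Index fragmentations into candidate matched pairs
#'
#' Groups fragmentations by identical canonical core and emits one
#' candidate pair for every unordered pair of distinct compounds sharing a
#' core with different exchanged fragments. Left/right within a pair is
#' lexicographic by compound identifier.
#'
#' @param frags Output of [enumerate_fragmentations()] over a whole
#'   dataset.
#' @return Tibble of candidate pairs: `cid_left`, `cid_right`, `core`,
#'   `frag_left`, `frag_right`, `core_heavy`, `frag_left_heavy`,
#'   `frag_right_heavy`, `delta_heavy`, `n_cuts`.
#' @export
index_pairs <- function(frags) {
  f <- dplyr::distinct(tibble::as_tibble(frags))
  pairs <- dplyr::inner_join(
    f, f, by = c("core", "core_heavy", "n_cuts"),
    suffix = c("_l", "_r"), relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$cid_l < .data$cid_r,
                  .data$fragment_l != .data$fragment_r) |>
    dplyr::transmute(
      cid_left = .data$cid_l, cid_right = .data$cid_r,
      core = .data$core,
      frag_left = .data$fragment_l, frag_right = .data$fragment_r,
      core_heavy = .data$core_heavy,
      frag_left_heavy = .data$frag_heavy_l,
      frag_right_heavy = .data$frag_heavy_r,
      delta_heavy = abs(.data$frag_heavy_l - .data$frag_heavy_r),
      n_cuts = .data$n_cuts
    ) |>
    dplyr::distinct()
  pairs
}

#' Apply the size restrictions to candidate pairs
#'
#' A pair is retained iff (1) the invariant core has at least `core_ratio`
#' times the heavy atoms of each exchanged fragment, (2) each exchanged
#' fragment has at most `max_frag_heavy` heavy atoms, and (3) the
#' heavy-atom difference between the exchanged fragments is at most
#' `max_delta`. Boundaries are inclusive. Rejections carry the first rule
#' that failed.
#'
#' @param pairs Candidate pairs from [index_pairs()].
#' @param core_ratio,max_frag_heavy,max_delta The three size restrictions
#'   (defaults 2, 13 and 8 heavy atoms).
#' @return `pairs` with logical `retained` and `reject_reason` columns.
#' @export
size_filter <- function(pairs, core_ratio = 2, max_frag_heavy = 13L,
                        max_delta = 8L) {
  pairs |>
    tibble::as_tibble() |>
    dplyr::mutate(
      reject_reason = dplyr::case_when(
        core_heavy < core_ratio * pmax(frag_left_heavy, frag_right_heavy) ~
          "core_ratio",
        pmax(frag_left_heavy, frag_right_heavy) > max_frag_heavy ~
          "frag_size",
        delta_heavy > max_delta ~ "delta",
        TRUE ~ NA_character_
      ),
      retained = is.na(.data$reject_reason)
    )
}

#' Reduce candidates to one MMP per compound pair
#'
#' Among the retained candidate cuts of each unordered compound pair, keeps
#' the one with the smallest heavy-atom deviation between the exchanged
#' fragments; remaining ties are broken by a seeded random choice. The
#' number of surviving pairs does not depend on the seed, only the
#' representative cut may.
#'
#' @param pairs Candidate pairs (with `retained` column from
#'   [size_filter()], or assumed all retained if absent).
#' @param seed Integer seed for the tie-break.
#' @return Tibble with exactly one row per compound pair.
#' @export
deduplicate_pairs <- function(pairs, seed = 1L) {
  p <- tibble::as_tibble(pairs)
  if ("retained" %in% names(p)) p <- dplyr::filter(p, .data$retained)
  if (nrow(p) == 0L) return(p)
  withr::with_seed(seed, {
    p |>
      dplyr::group_by(.data$cid_left, .data$cid_right) |>
      dplyr::filter(.data$delta_heavy == min(.data$delta_heavy)) |>
      dplyr::slice_sample(n = 1L) |>
      dplyr::ungroup()
  })
}

#' Classify MMPs by the binary outcomes of their members
#'
#' Both inactive gives `inactive_mmp`, both active gives `active_mmp`, and
#' one of each gives `activity_cliff` (an MMP-based activity cliff). The
#' classification is invariant under swapping the pair.
#'
#' @param pairs MMP tibble with `cid_left`, `cid_right`.
#' @param outcomes Data frame with `cid` and `outcome` in
#'   `{Active, Inactive}` (e.g. a curated `assay_tbl`).
#' @return `pairs` with a `category` column.
#' @export
classify_pairs <- function(pairs, outcomes) {
  lut <- dplyr::distinct(tibble::as_tibble(outcomes)[, c("cid", "outcome")])
  out <- pairs |>
    tibble::as_tibble() |>
    dplyr::left_join(dplyr::rename(lut, outcome_left = "outcome"),
                     by = c(cid_left = "cid")) |>
    dplyr::left_join(dplyr::rename(lut, outcome_right = "outcome"),
                     by = c(cid_right = "cid"))
  if (anyNA(out$outcome_left) || anyNA(out$outcome_right) ||
      !all(c(out$outcome_left, out$outcome_right) %in%
             c("Active", "Inactive"))) {
    stop("every pair member needs a binary outcome", call. = FALSE)
  }
  dplyr::mutate(out, category = dplyr::case_when(
    outcome_left == "Inactive" & outcome_right == "Inactive" ~ "inactive_mmp",
    outcome_left == "Active" & outcome_right == "Active" ~ "active_mmp",
    TRUE ~ "activity_cliff"
  ))
}

#' Generate classified MMPs for a curated dataset
#'
#' Convenience chain: [enumerate_fragmentations()], [index_pairs()],
#' [size_filter()], [deduplicate_pairs()], [classify_pairs()].
#'
#' @param ds A curated `assay_tbl` (columns `cid`, `smiles`, `outcome`).
#' @param max_cuts,core_ratio,max_frag_heavy,max_delta,seed See the stage
#'   functions.
#' @return MMP tibble with one classified pair per compound pair; the
#'   parameters and seed are attached as the `params` attribute.
#' @export
generate_mmps <- function(ds, max_cuts = 1L, core_ratio = 2,
                          max_frag_heavy = 13L, max_delta = 8L, seed = 1L) {
  mmps <- enumerate_fragmentations(ds, max_cuts = max_cuts) |>
    index_pairs() |>
    size_filter(core_ratio = core_ratio, max_frag_heavy = max_frag_heavy,
                max_delta = max_delta) |>
    deduplicate_pairs(seed = seed) |>
    classify_pairs(ds)
  attr(mmps, "params") <- list(
    max_cuts = max_cuts, core_ratio = core_ratio,
    max_frag_heavy = max_frag_heavy, max_delta = max_delta, seed = seed
  )
  mmps
}

#' Build the MMP network
#'
#' Nodes are compounds annotated with their outcome; edges are MMPs
#' annotated with their category.
#'
#' @param pairs Classified MMP tibble.
#' @param outcomes Optional data frame with `cid`, `outcome` used to
#'   annotate nodes (defaults to the outcomes carried by `pairs`).
#' @return An [igraph::graph] object.
#' @export
build_network <- function(pairs, outcomes = NULL) {
  p <- tibble::as_tibble(pairs)
  if (is.null(outcomes)) {
    outcomes <- dplyr::bind_rows(
      tibble::tibble(cid = p$cid_left, outcome = p$outcome_left %||% NA),
      tibble::tibble(cid = p$cid_right, outcome = p$outcome_right %||% NA)
    )
  }
  verts <- dplyr::distinct(tibble::as_tibble(outcomes)[, c("cid", "outcome")])
  verts <- dplyr::filter(verts, .data$cid %in% c(p$cid_left, p$cid_right))
  igraph::graph_from_data_frame(
    d = p[, intersect(c("cid_left", "cid_right", "category", "core"),
                      names(p))],
    directed = FALSE,
    vertices = verts
  )
}

#' Write an MMP network to GraphML or SIF
#'
#' @param graph An [build_network()] graph.
#' @param path Output path.
#' @param format `"graphml"` (default) or `"sif"` (tab-separated
#'   `left  category  right` lines).
#' @return Invisibly, `path`.
#' @export
write_network <- function(graph, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    cat_attr <- igraph::edge_attr(graph, "category")
    if (is.null(cat_attr)) cat_attr <- rep("mmp", nrow(el))
    writeLines(if (nrow(el)) {
      paste(el[, 1], cat_attr, el[, 2], sep = "\t")
    } else {
      character()
    }, path)
  }
  invisible(path)
}
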