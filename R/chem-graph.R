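# Internal molecular-graph layer.
#
# All structure perception (SMILES parsing, canonical SMILES writing) is
# delegated to OpenBabel via ChemmineOB; molecules are held in between as
# plain atom/bond tables parsed from V2000 molfiles, which is the
# representation the scaffold and fragmentation algorithms operate on.
# Coordinates are never used, so written molfiles carry zeros.

DUMMY_ELEMENTS <- c("*", "R", "R#")
NON_HEAVY <- c("H", "D", "T", DUMMY_ELEMENTS)

#' @noRd
new_mol <- function(elem, bonds, chg = NULL, iso = NULL, title = "") {
  n <- length(elem)
  list(
    elem = elem,
    bonds = bonds, # matrix/data.frame with columns a1, a2, order
    chg = if (is.null(chg)) integer(n) else chg,
    iso = if (is.null(iso)) integer(n) else iso,
    title = title
  )
}

mol_n_atoms <- function(mol) length(mol$elem)

mol_heavy_idx <- function(mol) which(!(mol$elem %in% NON_HEAVY))

mol_n_heavy <- function(mol) sum(!(mol$elem %in% NON_HEAVY))

#' Parse one V2000 molfile (character scalar or vector of lines) into a mol.
#' @noRd
parse_molfile <- function(lines) {
  if (length(lines) == 1L) lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) return(NULL)
  atom_lines <- lines[seq.int(5, length.out = na)]
  elem <- trimws(substr(atom_lines, 32, 34))
  bond_lines <- lines[seq.int(5 + na, length.out = nb)]
  bonds <- data.frame(
    a1 = as.integer(substr(bond_lines, 1, 3)),
    a2 = as.integer(substr(bond_lines, 4, 6)),
    order = as.integer(substr(bond_lines, 7, 9))
  )
  chg <- integer(na)
  iso <- integer(na)
  for (ln in grep("^M  (CHG|ISO)", lines, value = TRUE)) {
    toks <- strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]]
    vals <- as.integer(toks)
    cnt <- vals[1]
    pairs <- matrix(vals[-1][seq_len(2 * cnt)], ncol = 2, byrow = TRUE)
    if (startsWith(ln, "M  CHG")) chg[pairs[, 1]] <- pairs[, 2]
    else iso[pairs[, 1]] <- pairs[, 2]
  }
  new_mol(elem, bonds, chg, iso, title = trimws(lines[1]))
}

#' Serialize a mol back to V2000 text (zero coordinates).
#' @noRd
write_molfile <- function(mol, title = mol$title) {
  na <- mol_n_atoms(mol)
  nb <- nrow(mol$bonds)
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, mol$elem
  )
  bond_lines <- if (nb > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
  } else character()
  prop <- character()
  chg_at <- which(mol$chg != 0L)
  if (length(chg_at)) {
    prop <- c(prop, paste0(
      sprintf("M  CHG%3d", length(chg_at)),
      paste0(sprintf("%4d%4d", chg_at, mol$chg[chg_at]), collapse = "")
    ))
  }
  iso_at <- which(mol$iso != 0L)
  if (length(iso_at)) {
    prop <- c(prop, paste0(
      sprintf("M  ISO%3d", length(iso_at)),
      paste0(sprintf("%4d%4d", iso_at, mol$iso[iso_at]), collapse = "")
    ))
  }
  paste(c(
    title, " moacliff 2D", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
    atom_lines, bond_lines, prop, "M  END"
  ), collapse = "\n")
}

#' Batch OpenBabel conversion with per-item fallback.
#'
#' OpenBabel aborts a multi-record conversion at the first bad record, so on
#' a short read we re-run item by item and return NA for the offenders.
#' @noRd
ob_batch <- function(from, to, items, make_input, split_output) {
  n <- length(items)
  if (n == 0L) return(character())
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, source = make_input(items, seq_len(n))),
    error = function(e) ""
  )
  got <- split_output(out)
  if (length(got$value) == n && !anyNA(got$id) && identical(sort(got$id), seq_len(n))) {
    return(got$value[order(got$id)])
  }
  # fallback: one at a time
  vapply(seq_len(n), function(i) {
    o <- tryCatch(
      ChemmineOB::convertFormat(from, to, source = make_input(items[i], i)),
      error = function(e) ""
    )
    g <- split_output(o)
    if (length(g$value) == 1L) g$value else NA_character_
  }, character(1))
}

#' Canonical SMILES for a character vector; NA for unparseable entries.
#' @noRd
smiles_to_cansmi <- function(smiles) {
  res <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(res)
  vals <- ob_batch(
    "SMI", "CAN", smiles[ok],
    make_input = function(x, id) paste(paste(x, paste0("m", id)), collapse = "\n"),
    split_output = function(out) {
      lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      value <- trimws(vapply(parts, `[`, character(1), 1))
      idtok <- trimws(vapply(parts, function(p) if (length(p) > 1) p[2] else "", character(1)))
      id <- suppressWarnings(as.integer(sub("^m", "", idtok)))
      list(value = ifelse(nzchar(value), value, NA_character_), id = id)
    }
  )
  res[ok] <- vals
  res
}

#' Parse SMILES into mol objects (list; NULL elements for failures).
#' @noRd
mols_from_smiles <- function(smiles) {
  res <- vector("list", length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(res)
  sdf <- ob_batch(
    "SMI", "SDF", smiles[ok],
    make_input = function(x, id) paste(paste(x, paste0("m", id)), collapse = "\n"),
    split_output = function(out) {
      blocks <- strsplit(out, "\\$\\$\\$\\$\n?")[[1]]
      blocks <- blocks[nzchar(trimws(blocks))]
      id <- suppressWarnings(as.integer(sub("^\\s*m", "", vapply(
        strsplit(blocks, "\n", fixed = TRUE), `[`, character(1), 1
      ))))
      list(value = blocks, id = id)
    }
  )
  mols <- lapply(sdf, function(b) if (is.na(b)) NULL else parse_molfile(b))
  res[ok] <- mols
  res
}

#' Canonical SMILES for a list of mol objects (NA where NULL / failed).
#' @noRd
mols_to_cansmi <- function(mols) {
  res <- rep(NA_character_, length(mols))
  ok <- !vapply(mols, is.null, logical(1))
  if (!any(ok)) return(res)
  vals <- ob_batch(
    "SDF", "CAN", mols[ok],
    make_input = function(x, id) {
      paste0(paste(
        mapply(function(m, i) write_molfile(m, title = paste0("m", i)),
               x, id, SIMPLIFY = TRUE),
        collapse = "\n$$$$\n"
      ), "\n$$$$\n")
    },
    split_output = function(out) {
      lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      value <- trimws(vapply(parts, `[`, character(1), 1))
      idtok <- trimws(vapply(parts, function(p) if (length(p) > 1) p[2] else "", character(1)))
      id <- suppressWarnings(as.integer(sub("^m", "", idtok)))
      list(value = ifelse(nzchar(value), value, NA_character_), id = id)
    }
  )
  res[ok] <- vals
  res
}

#' Undirected igraph over all atoms (isolated atoms included).
#' @noRd
mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    mol$bonds[, c("a1", "a2")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(mol_n_atoms(mol)))
  )
}

#' Number of connected components of the molecular graph.
#' @noRd
mol_n_components <- function(mol) {
  if (mol_n_atoms(mol) == 0L) return(0L)
  as.integer(igraph::count_components(mol_igraph(mol)))
}

#' SSSR cardinality (circuit rank): bonds - atoms + components.
#' @noRd
mol_ring_count <- function(mol) {
  as.integer(nrow(mol$bonds) - mol_n_atoms(mol) + mol_n_components(mol))
}

#' Logical vector over bonds: TRUE if the bond lies in a ring.
#' @noRd
mol_ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  g <- mol_igraph(mol)
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nb)
  in_ring[as.integer(br)] <- FALSE
  in_ring
}

#' Induced sub-molecule on an atom index set (bonds renumbered).
#' @noRd
mol_subset <- function(mol, keep) {
  keep <- sort(unique(keep))
  map <- integer(mol_n_atoms(mol))
  map[keep] <- seq_along(keep)
  b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, , drop = FALSE]
  b$a1 <- map[b$a1]
  b$a2 <- map[b$a2]
  rownames(b) <- NULL
  new_mol(mol$elem[keep], b, mol$chg[keep], mol$iso[keep], mol$title)
}

#' Bemis-Murcko scaffold of a mol: ring systems, the linkers connecting
#' them, and atoms attached to ring/linker atoms by bonds of order >= 2.
#' Returns NULL for ringless molecules.
#' @noRd
mol_bm_scaffold <- function(mol) {
  in_ring_bond <- mol_ring_bonds(mol)
  if (!any(in_ring_bond)) return(NULL)
  n <- mol_n_atoms(mol)
  ring_atoms <- unique(c(mol$bonds$a1[in_ring_bond], mol$bonds$a2[in_ring_bond]))
  # iteratively prune terminal atoms; ring atoms are never terminal, and
  # what survives is the ring-and-linker framework
  alive <- rep(TRUE, n)
  repeat {
    b <- mol$bonds[alive[mol$bonds$a1] & alive[mol$bonds$a2], , drop = FALSE]
    deg <- tabulate(c(b$a1, b$a2), nbins = n)
    drop <- alive & deg <= 1L & !(seq_len(n) %in% ring_atoms)
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  framework <- which(alive)
  # re-attach atoms multiply bonded to a framework atom
  hi <- mol$bonds$order >= 2L
  add <- unique(c(
    mol$bonds$a1[hi & mol$bonds$a2 %in% framework],
    mol$bonds$a2[hi & mol$bonds$a1 %in% framework]
  ))
  mol_subset(mol, union(framework, add))
}

#' Cyclic skeleton: every atom to carbon, every bond to single, charges
#' and isotopes cleared.
#' @noRd
mol_csk <- function(mol) {
  m <- mol
  m$elem <- ifelse(m$elem %in% DUMMY_ELEMENTS, m$elem, "C")
  m$bonds$order <- 1L
  m$chg <- integer(length(m$elem))
  m$iso <- integer(length(m$elem))
  m
}

#' Indices of cuttable bonds: acyclic single bonds between heavy atoms.
#' @noRd
mol_cut_bonds <- function(mol) {
  heavy <- !(mol$elem %in% NON_HEAVY)
  in_ring <- mol_ring_bonds(mol)
  which(mol$bonds$order == 1L & !in_ring &
          heavy[mol$bonds$a1] & heavy[mol$bonds$a2])
}

#' Split a mol at one acyclic bond; returns the two sides, each with a
#' dummy attachment atom ("*", optionally isotope-labelled) bonded to the
#' former cut position.
#' @noRd
mol_split_bond <- function(mol, bond_idx, label = 0L) {
  u <- mol$bonds$a1[bond_idx]
  v <- mol$bonds$a2[bond_idx]
  b <- mol$bonds[-bond_idx, , drop = FALSE]
  m2 <- new_mol(mol$elem, b, mol$chg, mol$iso, mol$title)
  comp <- igraph::components(mol_igraph(m2))$membership
  side_u <- which(comp == comp[[u]])
  side_v <- which(comp == comp[[v]])
  list(
    add_dummy(mol_subset(m2, side_u), match(u, sort(side_u)), label),
    add_dummy(mol_subset(m2, side_v), match(v, sort(side_v)), label)
  )
}

#' @noRd
add_dummy <- function(mol, at, label = 0L) {
  n <- mol_n_atoms(mol)
  mol$elem <- c(mol$elem, "*")
  mol$chg <- c(mol$chg, 0L)
  mol$iso <- c(mol$iso, as.integer(label))
  mol$bonds <- rbind(mol$bonds, data.frame(a1 = at, a2 = n + 1L, order = 1L))
  mol
}
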