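# Internal molecular graph layer.
#
# Molecules and fragments are held as plain atom/bond tables ("molgraph").
# All chemistry perception (SMILES parsing, canonicalisation, aromaticity,
# InChIKey generation) is delegated to OpenBabel via ChemmineOB; this file
# only shuttles structures between SMILES, V2000 molblocks and the tabular
# graph form. Attachment points of fragments are wildcard atoms ("*") whose
# isotope field carries the attachment label (1..3), because isotopes are the
# one annotation that survives both SMILES and molblock round-trips.

OB_AVAILABLE <- NULL

#' @importFrom ChemmineOB convertFormat
ob_convert <- function(from, to, text, options = NULL) {
  out <- if (is.null(options)) {
    ChemmineOB::convertFormat(from, to, text)
  } else {
    ChemmineOB::convertFormat(from, to, text, options = options)
  }
  out <- strsplit(out, "\n", fixed = TRUE)[[1]]
  trimws(out)
}

# OpenBabel reports parse failures on stderr and returns empty output; a
# single-molecule conversion therefore either yields one line or character(0).
ob_convert1 <- function(from, to, text, options = NULL) {
  out <- ob_convert(from, to, text, options = options)
  out <- out[nzchar(out)]
  if (length(out) == 0L) NA_character_ else out[[1L]]
}

new_molgraph <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = integer())
}

# -- V2000 molblock <-> molgraph ---------------------------------------------
# ChemmineR's SDF container drops the M ISO block that carries attachment
# labels, so the few fixed-width fields needed here are read directly.

parse_molblock <- function(lines) {
  counts <- lines[4L]
  n_atoms <- as.integer(substr(counts, 1L, 3L))
  n_bonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(n_atoms) || is.na(n_bonds)) {
    stop("malformed molblock counts line: ", counts)
  }
  atom_lines <- lines[seq_len(n_atoms) + 4L]
  elem <- trimws(substr(atom_lines, 32L, 34L))
  atoms <- data.frame(
    elem = elem,
    charge = 0L,
    iso = 0L
  )
  if (n_bonds > 0L) {
    bond_lines <- lines[seq_len(n_bonds) + 4L + n_atoms]
    bonds <- data.frame(
      a1 = as.integer(substr(bond_lines, 1L, 3L)),
      a2 = as.integer(substr(bond_lines, 4L, 6L)),
      order = as.integer(substr(bond_lines, 7L, 9L))
    )
  } else {
    bonds <- empty_bonds()
  }
  prop <- lines[seq(5L + n_atoms + n_bonds, length(lines))]
  for (ln in prop[startsWith(prop, "M  ")]) {
    key <- substr(ln, 4L, 6L)
    if (!key %in% c("CHG", "ISO")) next
    n <- as.integer(substr(ln, 7L, 9L))
    for (i in seq_len(n)) {
      off <- 10L + (i - 1L) * 8L
      idx <- as.integer(substr(ln, off, off + 3L))
      val <- as.integer(substr(ln, off + 4L, off + 7L))
      if (key == "CHG") atoms$charge[idx] <- val else atoms$iso[idx] <- val
    }
  }
  new_molgraph(atoms, bonds)
}

fmt_i3 <- function(x) formatC(x, width = 3L, format = "d")

write_molblock <- function(g, title = "") {
  atoms <- g$atoms
  bonds <- g$bonds
  header <- c(title, "  mmpamp", "")
  counts <- paste0(fmt_i3(nrow(atoms)), fmt_i3(nrow(bonds)),
                   "  0  0  0  0  0  0  0  0999 V2000")
  atom_lines <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        atoms$elem)
  bond_lines <- if (nrow(bonds) > 0L) {
    paste0(fmt_i3(bonds$a1), fmt_i3(bonds$a2), fmt_i3(bonds$order),
           "  0  0  0  0")
  } else character()
  fmt_i4 <- function(x) formatC(x, width = 4L, format = "d")
  # at most 8 (index, value) entries per M-line
  prop_lines <- function(key, idx, val) {
    unlist(lapply(split(seq_along(idx), ceiling(seq_along(idx) / 8L)),
                  function(ch) {
                    paste0("M  ", key, fmt_i3(length(ch)),
                           paste0(fmt_i4(idx[ch]), fmt_i4(val[ch]),
                                  collapse = ""))
                  }))
  }
  prop <- character()
  chg <- which(atoms$charge != 0L)
  if (length(chg)) {
    prop <- c(prop, prop_lines("CHG", chg, atoms$charge[chg]))
  }
  iso <- which(atoms$iso != 0L)
  if (length(iso)) {
    prop <- c(prop, prop_lines("ISO", iso, atoms$iso[iso]))
  }
  paste(c(header, counts, atom_lines, bond_lines, prop, "M  END", "$$$$"),
        collapse = "\n")
}

mol_from_smiles <- function(smi) {
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", smi)
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  parse_molblock(lines)
}

smiles_from_mol <- function(g) {
  ob_convert1("SDF", "CAN", write_molblock(g))
}

# -- graph utilities ---------------------------------------------------------

heavy_atom_count <- function(g) {
  sum(!g$atoms$elem %in% c("*", "H"))
}

#' @importFrom igraph graph_from_data_frame bridges components V
mol_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$bonds)) g$bonds[, c("a1", "a2")] else data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(g$atoms)))
  )
}

# Indices (into g$bonds) of bonds not contained in any ring.
acyclic_bond_indices <- function(g) {
  if (nrow(g$bonds) == 0L) return(integer())
  ig <- mol_igraph(g)
  br <- igraph::bridges(ig)
  # igraph returns an edge sequence ordered as supplied, so positional ids map
  # straight back onto rows of g$bonds
  as.integer(br)
}

# Component membership after deleting the given bond rows.
components_without_bonds <- function(g, drop_bonds) {
  keep <- setdiff(seq_len(nrow(g$bonds)), drop_bonds)
  ig <- igraph::graph_from_data_frame(
    d = g$bonds[keep, c("a1", "a2"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(g$atoms)))
  )
  igraph::components(ig)$membership
}

graph_is_connected <- function(g) {
  if (nrow(g$atoms) <= 1L) return(TRUE)
  igraph::components(mol_igraph(g))$no == 1L
}

# Maximum usual valence per element; used only to discard nonsense products
# before handing structures back to OpenBabel.
MAX_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5,
                 S = 6, Cl = 1, Br = 1, I = 1)

bond_order_sums <- function(g) {
  s <- numeric(nrow(g$atoms))
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[i]
      if (o == 4L) o <- 1.5
      s[g$bonds$a1[i]] <- s[g$bonds$a1[i]] + o
      s[g$bonds$a2[i]] <- s[g$bonds$a2[i]] + o
    }
  }
  s
}

# Implicit hydrogen count per heavy atom (0 for wildcards and unknown
# elements). Charges shift the allowed valence by their sign for the common
# organic cations/anions (e.g. N+ has 4, O- has 1).
implicit_h_counts <- function(g) {
  sums <- bond_order_sums(g)
  vapply(seq_len(nrow(g$atoms)), function(i) {
    el <- g$atoms$elem[i]
    if (el %in% c("*", "H")) return(0L)
    v <- MAX_VALENCE[el]
    if (is.na(v)) return(0L)
    v <- v + g$atoms$charge[i]
    max(0L, as.integer(floor(v - sums[i])))
  }, integer(1))
}

valence_ok <- function(g) {
  sums <- bond_order_sums(g)
  for (i in seq_len(nrow(g$atoms))) {
    el <- g$atoms$elem[i]
    if (el == "*") next
    v <- MAX_VALENCE[el]
    if (is.na(v)) next
    if (sums[i] > v + max(0L, g$atoms$charge[i])) return(FALSE)
  }
  TRUE
}

# Extract the sub-molgraph on a set of atom indices, returning the graph and
# the old->new index map.
subgraph_atoms <- function(g, atom_idx) {
  atom_idx <- sort(atom_idx)
  map <- integer(nrow(g$atoms))
  map[atom_idx] <- seq_along(atom_idx)
  keep <- g$bonds$a1 %in% atom_idx & g$bonds$a2 %in% atom_idx
  bonds <- g$bonds[keep, , drop = FALSE]
  bonds$a1 <- map[bonds$a1]
  bonds$a2 <- map[bonds$a2]
  rownames(bonds) <- NULL
  list(graph = new_molgraph(g$atoms[atom_idx, , drop = FALSE][, c("elem", "charge", "iso")],
                            bonds),
       map = map)
}

# Append a wildcard atom bonded to `at` with attachment label `label`.
add_attachment <- function(g, at, label) {
  g$atoms <- rbind(g$atoms,
                   data.frame(elem = "*", charge = 0L, iso = as.integer(label)))
  g$bonds <- rbind(g$bonds,
                   data.frame(a1 = at, a2 = nrow(g$atoms), order = 1L))
  rownames(g$atoms) <- NULL
  rownames(g$bonds) <- NULL
  g
}
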