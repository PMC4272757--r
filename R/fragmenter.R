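# Single-, double- and triple-cut fragmentation with canonical fragment keys.
#
# A fragmentation splits a molecule into a variable part (the fragment that
# differs between the members of a matched pair) and a scaffold (the
# unaffected context). Cuts are made only at acyclic single bonds between two
# heavy atoms, so rings are never opened. For multi-cut fragmentations the
# variable part is the single connected component incident to every cut bond
# (the linker / core being replaced) and the scaffold is the remaining
# peripheral component(s), written dot-separated.
#
# Fragment notation: canonical SMILES with attachment points written as
# labelled wildcards "[*:1]".."[*:3]". Internally labels ride in the isotope
# field ("[1*]") because isotopes survive SMILES/molblock round-trips.

H_FRAGMENT_NOTATION <- "[*:1][H]"

iso_to_notation <- function(smi) {
  gsub("\\[([1-9])\\*\\]", "[*:\\1]", smi)
}

notation_to_iso <- function(notation) {
  gsub("\\[\\*:([1-9])\\]", "[\\1*]", notation)
}

fragment_key <- function(notation, attachment_count, atom_count) {
  list(notation = notation,
       attachment_count = as.integer(attachment_count),
       atom_count = as.integer(atom_count))
}

wildcard_indices <- function(g) which(g$atoms$elem == "*")

# Canonical SMILES of a fragment graph whose wildcards already carry their
# labels in the iso column.
fragment_notation <- function(g) {
  smi <- smiles_from_mol(g)
  if (is.na(smi)) stop("fragment canonicalisation failed")
  iso_to_notation(smi)
}

# Environment string of one attachment point: canonical SMILES with a probe
# isotope on that wildcard only. Two attachment points of a fragment get equal
# strings exactly when they are related by a graph automorphism.
attachment_env_string <- function(g, wc_index) {
  g$atoms$iso[wildcard_indices(g)] <- 0L
  g$atoms$iso[wc_index] <- 9L
  smi <- smiles_from_mol(g)
  if (is.na(smi)) stop("fragment canonicalisation failed")
  smi
}

perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  if (n == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(perms_of(n - 1L), function(p) {
      rest <- setdiff(seq_len(n), i)
      c(i, rest[p])
    })
  }))
}

# Deterministic attachment labelling for a scaffold/variable split.
#
# Scaffold attachment points are ranked by their environment strings; label 1
# goes to the lexicographically smallest environment. Ties (symmetry-
# equivalent attachment points) are broken by choosing, among the tied label
# assignments, the one that minimises the variable fragment's notation, so
# the same chemical fragmentation always produces byte-identical keys.
#
# `scaf` and `vari` are molgraphs whose j-th wildcard atoms correspond to the
# j-th cut bond.
canonical_split_keys <- function(scaf, vari) {
  wc_s <- wildcard_indices(scaf)
  wc_v <- wildcard_indices(vari)
  k <- length(wc_s)
  stopifnot(k == length(wc_v), k >= 1L, k <= 3L)
  if (k == 1L) {
    scaf$atoms$iso[wc_s] <- 1L
    vari$atoms$iso[wc_v] <- 1L
    return(list(scaffold = fragment_key(fragment_notation(scaf), 1L,
                                        heavy_atom_count(scaf)),
                variable = fragment_key(fragment_notation(vari), 1L,
                                        heavy_atom_count(vari))))
  }
  env <- vapply(wc_s, function(w) attachment_env_string(scaf, w), character(1))
  ord <- order(env)             # ord[l] = cut index receiving label l
  tie_ok <- function(assign) all(env[assign] == env[ord])
  candidates <- Filter(tie_ok, lapply(perms_of(k), function(p) ord[p]))
  best <- NULL
  for (assign in candidates) {
    v <- vari
    v$atoms$iso[wc_v[assign]] <- seq_len(k)
    nv <- fragment_notation(v)
    if (is.null(best) || nv < best$notation) {
      best <- list(notation = nv, assign = assign)
    }
  }
  scaf$atoms$iso[wc_s[best$assign]] <- seq_len(k)
  list(scaffold = fragment_key(fragment_notation(scaf), k,
                               heavy_atom_count(scaf)),
       variable = fragment_key(best$notation, k, heavy_atom_count(vari)))
}

#' Breakable bonds of a molecule
#'
#' A bond is breakable when it is a single bond between two heavy atoms and
#' does not belong to any ring; these are the only bonds the fragmenter cuts.
#'
#' @param smiles a single (standardized) SMILES string.
#' @return data.frame with columns `a1`, `a2` (atom indices in the canonical
#'   molblock atom order).
#' @export
breakable_bonds <- function(smiles) {
  g <- mol_from_smiles(smiles)
  if (is.null(g)) stop("unparseable structure: ", smiles)
  idx <- breakable_bond_indices(g)
  out <- g$bonds[idx, c("a1", "a2"), drop = FALSE]
  rownames(out) <- NULL
  out
}

breakable_bond_indices <- function(g) {
  if (nrow(g$bonds) == 0L) return(integer())
  acyclic <- acyclic_bond_indices(g)
  heavy <- !g$atoms$elem %in% c("*", "H")
  keep <- g$bonds$order == 1L &
    heavy[g$bonds$a1] & heavy[g$bonds$a2]
  intersect(acyclic, which(keep))
}

# Build the (scaffold, variable) graphs for one cut-set. Returns NULL when the
# cut-set does not produce a valid split.
split_by_cutset <- function(g, cutset, max_variable_atoms) {
  memb <- components_without_bonds(g, cutset)
  ends <- cbind(g$bonds$a1[cutset], g$bonds$a2[cutset])
  k <- length(cutset)
  heavy <- !g$atoms$elem %in% c("*", "H")
  comp_sizes <- tapply(heavy, memb, sum)
  if (k == 1L) {
    c1 <- memb[ends[1L, 1L]]
    c2 <- memb[ends[1L, 2L]]
    s1 <- comp_sizes[[as.character(c1)]]
    s2 <- comp_sizes[[as.character(c2)]]
    if (s1 == s2) return(NULL)       # strict size rule: no valid orientation
    var_comp <- if (s1 < s2) c1 else c2
  } else {
    touched <- lapply(seq_len(k), function(i) unique(memb[ends[i, ]]))
    cand <- Reduce(intersect, touched)
    if (length(cand) != 1L) return(NULL)
    var_comp <- cand
  }
  var_atoms_n <- comp_sizes[[as.character(var_comp)]]
  scaf_atoms_n <- sum(comp_sizes) - var_atoms_n
  if (var_atoms_n > max_variable_atoms || var_atoms_n >= scaf_atoms_n) {
    return(NULL)
  }
  scaf_sub <- subgraph_atoms(g, which(memb != var_comp))
  vari_sub <- subgraph_atoms(g, which(memb == var_comp))
  for (i in seq_len(k)) {
    in_var <- memb[ends[i, ]] == var_comp
    if (sum(in_var) != 1L) return(NULL)   # cut must join the two sides
    v_end <- ends[i, in_var]
    s_end <- ends[i, !in_var]
    scaf_sub$graph <- add_attachment(scaf_sub$graph, scaf_sub$map[s_end], i)
    vari_sub$graph <- add_attachment(vari_sub$graph, vari_sub$map[v_end], i)
  }
  list(scaffold = scaf_sub$graph, variable = vari_sub$graph)
}

#' Enumerate fragmentations of a molecule
#'
#' Emits one record per valid cut-set of 1..`max_cuts` breakable bonds, plus
#' one single-cut record per symmetry-distinct hydrogen position with the
#' explicit-hydrogen fragment `[*:1][H]` as the variable part (these enable
#' H -> X transformations). Records are deduplicated on
#' (scaffold, variable) notation; symmetry-equivalent cuts therefore collapse.
#'
#' The variable part must have at most `max_variable_atoms` heavy atoms and
#' strictly fewer than the scaffold. Molecules with more than
#' `max_breakable_bonds` breakable bonds are skipped with a warning and yield
#' zero records (attribute `skipped` is set).
#'
#' @param smiles a single standardized SMILES string.
#' @param max_cuts number of simultaneous cuts to consider (1..3).
#' @param max_variable_atoms size cap for the variable fragment.
#' @param max_breakable_bonds combinatorial-explosion guard.
#' @param hydrogen_records emit the H-replacement records (default `TRUE`).
#' @return data.frame with columns `scaffold`, `variable`, `n_cuts`,
#'   `scaffold_atoms`, `variable_atoms`.
#' @export
enumerate_fragmentations <- function(smiles, max_cuts = 3L,
                                     max_variable_atoms = 10L,
                                     max_breakable_bonds = 40L,
                                     hydrogen_records = TRUE) {
  stopifnot(max_cuts >= 1L, max_cuts <= 3L)
  g <- mol_from_smiles(smiles)
  if (is.null(g)) stop("unparseable structure: ", smiles)
  empty <- data.frame(scaffold = character(), variable = character(),
                      n_cuts = integer(), scaffold_atoms = integer(),
                      variable_atoms = integer())
  bb <- breakable_bond_indices(g)
  if (length(bb) > max_breakable_bonds) {
    warning("molecule has ", length(bb), " breakable bonds (limit ",
            max_breakable_bonds, "); skipped: ", smiles)
    attr(empty, "skipped") <- TRUE
    return(empty)
  }
  rows <- list()
  for (k in seq_len(min(max_cuts, length(bb)))) {
    cutsets <- utils::combn(bb, k, simplify = FALSE)
    for (cs in cutsets) {
      sp <- split_by_cutset(g, cs, max_variable_atoms)
      if (is.null(sp)) next
      keys <- canonical_split_keys(sp$scaffold, sp$variable)
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = keys$scaffold$notation,
        variable = keys$variable$notation,
        n_cuts = k,
        scaffold_atoms = keys$scaffold$atom_count,
        variable_atoms = keys$variable$atom_count)
    }
  }
  if (hydrogen_records) {
    hc <- implicit_h_counts(g)
    for (at in which(hc >= 1L)) {
      scaf <- add_attachment(g, at, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = fragment_notation(scaf),
        variable = H_FRAGMENT_NOTATION,
        n_cuts = 1L,
        scaffold_atoms = heavy_atom_count(g),
        variable_atoms = 0L)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("scaffold", "variable")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonicalise a fragment notation
#'
#' Re-canonicalises a fragment written in the `[*:1]` wildcard dialect so that
#' the same chemical fragment always yields byte-identical notation. For
#' multi-attachment fragments the labels are re-assigned to the permutation
#' that minimises the canonical string, so swapped-label inputs of the same
#' linker collapse.
#'
#' @param notation fragment string with 1-3 labelled wildcard attachment
#'   points.
#' @return a fragment key: list with `notation`, `attachment_count`,
#'   `atom_count`.
#' @export
canonical_fragment <- function(notation) {
  if (notation == H_FRAGMENT_NOTATION || notation %in% c("[H][*:1]", "[*:1][H]")) {
    return(fragment_key(H_FRAGMENT_NOTATION, 1L, 0L))
  }
  g <- fragment_graph(notation)
  wc <- wildcard_indices(g)
  k <- length(wc)
  if (k < 1L) stop("fragment has no attachment point: ", notation)
  if (k > 3L) stop("fragment has ", k, " attachment points (max 3): ",
                   notation)
  best <- NULL
  for (p in perms_of(k)) {
    gg <- g
    gg$atoms$iso[wc[p]] <- seq_len(k)
    nn <- fragment_notation(gg)
    if (is.null(best) || nn < best) best <- nn
  }
  fragment_key(best, k, heavy_atom_count(g))
}

# Parse a fragment notation into a molgraph (wildcard labels in iso column).
fragment_graph <- function(notation) {
  if (notation == H_FRAGMENT_NOTATION) {
    return(new_molgraph(
      data.frame(elem = c("*", "H"), charge = 0L, iso = c(1L, 0L)),
      data.frame(a1 = 1L, a2 = 2L, order = 1L)))
  }
  g <- mol_from_smiles(notation_to_iso(notation))
  if (is.null(g)) stop("unparseable fragment: ", notation)
  g
}

#' Reassemble a scaffold and a variable fragment
#'
#' Joins the two fragments at matching attachment labels with single bonds and
#' returns the canonical SMILES of the resulting molecule. Inverse of
#' [enumerate_fragmentations()]: reassembling any emitted record reproduces
#' the parent's canonical structure.
#'
#' @param scaffold,variable fragment notations with matching labels.
#' @return canonical SMILES string.
#' @export
reassemble_fragments <- function(scaffold, variable) {
  gs <- fragment_graph(scaffold)
  if (variable == H_FRAGMENT_NOTATION) {
    # removing the wildcard restores an implicit hydrogen at the cut atom
    g <- subgraph_atoms(gs, setdiff(seq_len(nrow(gs$atoms)),
                                    wildcard_indices(gs)))$graph
    smi <- smiles_from_mol(g)
    if (is.na(smi)) stop("reassembly produced an invalid structure")
    return(smi)
  }
  gv <- fragment_graph(variable)
  n_s <- nrow(gs$atoms)
  atoms <- rbind(gs$atoms, gv$atoms)
  bonds <- rbind(gs$bonds,
                 data.frame(a1 = gv$bonds$a1 + n_s, a2 = gv$bonds$a2 + n_s,
                            order = gv$bonds$order))
  g <- new_molgraph(atoms, bonds)
  wc <- wildcard_indices(g)
  labels <- g$atoms$iso[wc]
  for (l in unique(labels)) {
    ends <- wc[labels == l]
    if (length(ends) != 2L) {
      stop("attachment label ", l, " does not pair up")
    }
    partner <- function(w) {
      b <- g$bonds[g$bonds$a1 == w | g$bonds$a2 == w, ]
      setdiff(c(b$a1, b$a2), w)[[1L]]
    }
    g$bonds <- rbind(g$bonds,
                     data.frame(a1 = partner(ends[1L]),
                                a2 = partner(ends[2L]), order = 1L))
  }
  keep <- setdiff(seq_len(nrow(g$atoms)), wc)
  g <- subgraph_atoms(g, keep)$graph
  smi <- smiles_from_mol(g)
  if (is.na(smi)) stop("reassembly produced an invalid structure")
  smi
}
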