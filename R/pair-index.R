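# Scaffold-keyed index, matched-pair identification and canonical
# transformations.

#' Build a matched-molecular-pair index
#'
#' Fragments every unique molecule (uniqueness tracked by InChIKey, so
#' duplicate structures under different ids are indexed once and aliased) and
#' stores the records keyed by scaffold notation. Molecules above the
#' breakable-bond limit are skipped and listed in `$skipped`.
#'
#' @param mols data.frame from [standardize_molecules()].
#' @param max_cuts,max_variable_atoms,max_breakable_bonds fragmentation
#'   limits (defaults 3, 10, 40).
#' @param hydrogen_records emit H-replacement records (default `TRUE`).
#' @return an object of class `mmp_index` with elements `molecules`,
#'   `fragmentations` (columns `mol_id`, `scaffold`, `variable`, `n_cuts`,
#'   `scaffold_atoms`, `variable_atoms`), `aliases`, `skipped`.
#' @export
build_index <- function(mols, max_cuts = 3L, max_variable_atoms = 10L,
                        max_breakable_bonds = 40L, hydrogen_records = TRUE) {
  if (anyDuplicated(mols$id)) {
    stop("duplicate molecule ids: ",
         paste(unique(mols$id[duplicated(mols$id)]), collapse = ", "))
  }
  first <- !duplicated(mols$unique_key)
  reps <- mols[first, , drop = FALSE]
  aliases <- mols[!first, c("id", "unique_key"), drop = FALSE]
  aliases$canonical_id <- reps$id[match(aliases$unique_key, reps$unique_key)]
  skipped <- character()
  frag_list <- vector("list", nrow(reps))
  for (i in seq_len(nrow(reps))) {
    f <- withCallingHandlers(
      enumerate_fragmentations(reps$smiles[i], max_cuts = max_cuts,
                               max_variable_atoms = max_variable_atoms,
                               max_breakable_bonds = max_breakable_bonds,
                               hydrogen_records = hydrogen_records),
      warning = function(w) invokeRestart("muffleWarning"))
    if (isTRUE(attr(f, "skipped"))) skipped <- c(skipped, reps$id[i])
    if (nrow(f)) f$mol_id <- reps$id[i]
    frag_list[[i]] <- f
  }
  frags <- do.call(rbind, frag_list[vapply(frag_list, nrow, integer(1)) > 0])
  if (is.null(frags)) {
    frags <- data.frame(scaffold = character(), variable = character(),
                        n_cuts = integer(), scaffold_atoms = integer(),
                        variable_atoms = integer(), mol_id = character())
  }
  rownames(frags) <- NULL
  structure(list(molecules = reps, fragmentations = frags,
                 aliases = aliases, skipped = skipped),
            class = "mmp_index")
}

#' @export
print.mmp_index <- function(x, ...) {
  cat("mmp_index:", nrow(x$molecules), "molecules,",
      nrow(x$fragmentations), "fragmentation records,",
      length(unique(x$fragmentations$scaffold)), "scaffold keys,",
      length(x$skipped), "skipped\n")
  invisible(x)
}

#' Find matched molecular pairs
#'
#' Two molecules form a matched pair when they share a scaffold key with
#' distinct variable fragments and their whole-molecule Tanimoto similarity
#' is at least `min_similarity`. Pair identity is unordered; records are
#' oriented deterministically (`mol_a` < `mol_b` by id). When one molecule
#' pair matches on several scaffolds (nested cuts), one record per scaffold
#' is emitted, all carrying the same `pair_group` id so downstream statistics
#' can count the molecule pair once per transformation.
#'
#' @param index an `mmp_index`.
#' @param min_similarity Tanimoto threshold in `[0, 1]` (default 0.5).
#' @param radius,n_bits fingerprint parameters (see [fingerprint()]).
#' @return data.frame with columns `mol_a`, `mol_b`, `scaffold`, `frag_a`,
#'   `frag_b`, `n_cuts`, `similarity`, `pair_group`.
#' @export
find_matched_pairs <- function(index, min_similarity = 0.5, radius = 2L,
                               n_bits = 2048L) {
  stopifnot(inherits(index, "mmp_index"),
            min_similarity >= 0, min_similarity <= 1)
  frags <- index$fragmentations
  empty <- data.frame(mol_a = character(), mol_b = character(),
                      scaffold = character(), frag_a = character(),
                      frag_b = character(), n_cuts = integer(),
                      similarity = numeric(), pair_group = character())
  if (nrow(frags) == 0L) return(empty)
  fps <- fingerprint_batch(index$molecules$smiles, radius = radius,
                           n_bits = n_bits)
  names(fps) <- index$molecules$id
  sim_cache <- new.env(parent = emptyenv())
  pair_sim <- function(a, b) {
    key <- paste(a, b, sep = "\r")
    got <- sim_cache[[key]]
    if (!is.null(got)) return(got)
    s <- tanimoto(fps[[a]], fps[[b]])
    sim_cache[[key]] <- s
    s
  }
  rows <- list()
  for (scaf in unique(frags$scaffold)) {
    sub <- frags[frags$scaffold == scaf, , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) {
      for (j in seq(i + 1L, nrow(sub))) {
        if (sub$mol_id[i] == sub$mol_id[j]) next
        if (sub$variable[i] == sub$variable[j]) next
        ord <- order(c(sub$mol_id[i], sub$mol_id[j]), method = "radix")
        ij <- c(i, j)[ord]
        a <- sub$mol_id[ij[1L]]; b <- sub$mol_id[ij[2L]]
        s <- pair_sim(a, b)
        if (s < min_similarity) next
        rows[[length(rows) + 1L]] <- data.frame(
          mol_a = a, mol_b = b, scaffold = scaf,
          frag_a = sub$variable[ij[1L]], frag_b = sub$variable[ij[2L]],
          n_cuts = sub$n_cuts[i], similarity = s,
          pair_group = paste(a, b, sep = "|"))
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold, out$mol_a, out$mol_b, out$frag_a,
                   out$frag_b, method = "radix"), , drop = FALSE]
  out <- out[!duplicated(out[, c("mol_a", "mol_b", "scaffold",
                                 "frag_a", "frag_b")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Relabel a fragment's attachment labels by permutation p (new label
# p[old label]) and re-canonicalise.
relabel_fragment <- function(notation, p) {
  if (notation == H_FRAGMENT_NOTATION) return(notation)
  g <- fragment_graph(notation)
  wc <- wildcard_indices(g)
  g$atoms$iso[wc] <- p[g$atoms$iso[wc]]
  fragment_notation(g)
}

# Canonical directed identity of the fragment replacement frag_a -> frag_b.
# The two notations share scaffold-consistent attachment labels; the same
# relabelling permutation is applied to both sides so the pairing of
# attachment points is preserved. Orientation: left <= right
# lexicographically; sign +1 when (frag_a, frag_b) runs left -> right.
transformation_key <- function(frag_a, frag_b, n_cuts) {
  if (n_cuts == 1L) {
    left <- min(frag_a, frag_b); right <- max(frag_a, frag_b)
    return(list(left = left, right = right,
                sign = if (frag_a == left) 1L else -1L))
  }
  best <- NULL
  for (p in perms_of(n_cuts)) {
    na <- relabel_fragment(frag_a, p)
    nb <- relabel_fragment(frag_b, p)
    left <- min(na, nb); right <- max(na, nb)
    key <- paste(left, right, sep = ">>")
    if (is.null(best) || key < best$key) {
      best <- list(key = key, left = left, right = right,
                   sign = if (na == left) 1L else -1L)
    }
  }
  best[c("left", "right", "sign")]
}

#' Extract canonical transformations from matched pairs
#'
#' Groups pairs by the canonical directed fragment replacement they realise.
#' Each transformation is oriented `left >> right` with
#' `left <= right` lexicographically; a pair whose change runs right-to-left
#' carries `sign = -1`. Total pair multiplicity is conserved: every input
#' pair is assigned to exactly one transformation.
#'
#' @param pairs data.frame from [find_matched_pairs()].
#' @return list with `transformations` (columns `transformation`, `left`,
#'   `right`, `n_cuts`, `n_pairs`) and `pairs` (the input plus
#'   `transformation` and `sign` columns).
#' @export
extract_transformations <- function(pairs) {
  if (nrow(pairs) == 0L) stop("no pairs supplied")
  keys <- vector("list", nrow(pairs))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    ck <- paste(pairs$frag_a[i], pairs$frag_b[i], pairs$n_cuts[i], sep = "\r")
    got <- cache[[ck]]
    if (is.null(got)) {
      got <- transformation_key(pairs$frag_a[i], pairs$frag_b[i],
                                pairs$n_cuts[i])
      cache[[ck]] <- got
    }
    keys[[i]] <- got
  }
  left <- vapply(keys, `[[`, character(1), "left")
  right <- vapply(keys, `[[`, character(1), "right")
  sign <- vapply(keys, `[[`, integer(1), "sign")
  key <- paste(left, right, sep = ">>")
  uniq <- sort(unique(key), method = "radix")
  tid <- paste0("T", formatC(seq_along(uniq), width = 4, flag = "0"))
  names(tid) <- uniq
  pairs$transformation <- unname(tid[key])
  pairs$sign <- sign
  tf <- data.frame(
    transformation = unname(tid),
    left = left[match(uniq, key)],
    right = right[match(uniq, key)],
    n_cuts = pairs$n_cuts[match(uniq, key)],
    n_pairs = as.integer(table(pairs$transformation)[tid]))
  rownames(tf) <- NULL
  list(transformations = tf, pairs = pairs)
}

#' Per-pair endpoint deltas
#'
#' Looks up the endpoint value of each pair member and forms the pair delta.
#' When a molecule carries both an experimental and a predicted value for the
#' endpoint, the experimental one wins; predictions only fill gaps. A pair is
#' labelled `provenance = "experimental"` only when both sides are
#' experimental. Out-of-domain predictions are excluded (the pair is dropped)
#' unless `include_out_of_domain` is set.
#'
#' @param pairs data.frame of pairs (optionally already carrying
#'   `transformation`/`sign` columns, which are passed through).
#' @param endpoints endpoint table (see [read_endpoint_table()]).
#' @param endpoint endpoint name to extract.
#' @param include_out_of_domain keep pairs relying on out-of-domain
#'   predictions (default `FALSE`).
#' @return the pairs data.frame augmented with `kind`, `value_a`, `value_b`,
#'   `delta` (continuous: `value_b - value_a`), `provenance`, `unc_a`,
#'   `unc_b`, `uncertainty` (combined standard error, continuous).
#' @export
pair_deltas <- function(pairs, endpoints, endpoint,
                        include_out_of_domain = FALSE) {
  ep <- endpoints[endpoints$endpoint == endpoint, , drop = FALSE]
  if (nrow(ep) == 0L) stop("no endpoint rows for: ", endpoint)
  kinds <- unique(ep$kind)
  if (length(kinds) != 1L) {
    stop("endpoint kind inconsistent for ", endpoint, ": ",
         paste(kinds, collapse = ", "))
  }
  kind <- kinds[[1L]]
  # experimental rows first so the match() lookup prefers them
  ep <- ep[order(ep$source != "experimental"), , drop = FALSE]
  if (!include_out_of_domain) {
    ep <- ep[ep$in_domain, , drop = FALSE]
  }
  ia <- match(pairs$mol_a, ep$id)
  ib <- match(pairs$mol_b, ep$id)
  keep <- !is.na(ia) & !is.na(ib)
  out <- pairs[keep, , drop = FALSE]
  ia <- ia[keep]; ib <- ib[keep]
  if (nrow(out) == 0L) {
    extra <- c("kind", "value_a", "value_b", "source_a", "source_b",
               "unc_a", "unc_b", "provenance", "delta", "uncertainty")
    for (col in extra) out[[col]] <- character()
    return(out)
  }
  out$kind <- kind
  out$value_a <- ep$value[ia]
  out$value_b <- ep$value[ib]
  out$source_a <- ep$source[ia]
  out$source_b <- ep$source[ib]
  out$unc_a <- ep$uncertainty[ia]
  out$unc_b <- ep$uncertainty[ib]
  out$provenance <- ifelse(out$source_a == "experimental" &
                             out$source_b == "experimental",
                           "experimental", "predicted")
  if (kind == "continuous") {
    out$value_a <- as.numeric(out$value_a)
    out$value_b <- as.numeric(out$value_b)
    out$delta <- out$value_b - out$value_a
    out$uncertainty <- sqrt(out$unc_a^2 + out$unc_b^2)
  } else {
    out$delta <- NA_real_
    out$uncertainty <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Export transformations as SMIRKS-like strings
#'
#' Writes one `left>>right` line per transformation for use in external
#' tools.
#' @param transformations data.frame from [extract_transformations()].
#' @param path output file.
#' @export
write_transformations <- function(transformations, path) {
  writeLines(paste0(transformations$left, ">>", transformations$right), path)
}

#' Export a pair table
#' @param pairs pair data.frame (any stage).
#' @param path output file.
#' @param sep separator (default tab).
#' @export
write_pairs_table <- function(pairs, path, sep = "\t") {
  utils::write.table(pairs, path, sep = sep, row.names = FALSE, quote = FALSE)
}
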