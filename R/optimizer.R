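# Transformation-driven molecular optimization: apply significant
# transformations to a target molecule, filter products by similarity, and
# score hits with a predictor.

# Per-atom aromaticity via OpenBabel: isotope-tag every atom, canonicalise,
# and read back which atoms print as lowercase (aromatic) SMILES symbols.
AROMATIC_SYMBOLS <- c("c", "n", "o", "s", "p", "b", "se", "as")

atom_aromatic <- function(g) {
  n <- nrow(g$atoms)
  gg <- g
  gg$atoms$iso <- seq_len(n) + 100L
  smi <- smiles_from_mol(gg)
  arom <- rep(FALSE, n)
  if (is.na(smi)) return(arom)
  m <- gregexpr("\\[(\\d+)(se|as|[A-Za-z*])", smi)[[1]]
  if (m[1L] == -1L) return(arom)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    tok <- substr(smi, starts[i] + 1L, starts[i] + lens[i] - 1L)
    iso <- as.integer(gsub("[^0-9]", "", tok))
    sym <- gsub("[0-9]", "", tok)
    idx <- iso - 100L
    if (!is.na(idx) && idx >= 1L && idx <= n) {
      arom[idx] <- sym %in% AROMATIC_SYMBOLS
    }
  }
  arom
}

# Vertex / edge colour model for VF2 matching: atoms match on
# (element, charge, aromaticity); bonds match on order, with all aromatic
# ring bonds sharing one colour so kekule alternation does not block matches.
match_colors <- function(g) {
  arom <- atom_aromatic(g)
  acy <- acyclic_bond_indices(g)
  in_ring <- !(seq_len(nrow(g$bonds)) %in% acy)
  both_arom <- arom[g$bonds$a1] & arom[g$bonds$a2]
  vkey <- paste(g$atoms$elem, g$atoms$charge, arom)
  ekey <- ifelse(in_ring & both_arom, "aromatic", as.character(g$bonds$order))
  list(vkey = vkey, ekey = ekey, aromatic = arom, ring = in_ring)
}

#' Apply a transformation to a molecule
#'
#' Replaces every severable embedding of the source fragment (the `left`
#' side when `direction = 1`, the `right` side when `-1`) by the target
#' fragment, attaching it at the labelled points. An embedding is severable
#' when the fragment's atoms connect to the rest of the molecule only through
#' acyclic single bonds at its attachment atoms, exactly one per attachment
#' point — the mirror image of how the fragmenter cuts. Products are
#' standardized and deduplicated on their unique key; structures with
#' impossible valences are discarded silently.
#'
#' @param smiles target molecule (standardized SMILES).
#' @param left,right fragment notations of the transformation.
#' @param direction `1` applies left -> right, `-1` right -> left.
#' @return data.frame of products: `smiles`, `unique_key` (possibly 0 rows).
#' @export
apply_transformation <- function(smiles, left, right, direction = 1L) {
  source_not <- if (direction >= 0) left else right
  target_not <- if (direction >= 0) right else left
  g <- mol_from_smiles(smiles)
  if (is.null(g)) stop("unparseable structure: ", smiles)
  tg <- fragment_graph(target_not)
  products <- if (source_not == H_FRAGMENT_NOTATION) {
    apply_at_hydrogens(g, tg)
  } else {
    apply_at_embeddings(g, fragment_graph(source_not), tg)
  }
  products <- unique(products[!is.na(products)])
  if (!length(products)) {
    return(data.frame(smiles = character(), unique_key = character()))
  }
  keys <- vapply(products, function(s) {
    k <- ob_convert1("SMI", "INCHIKEY", s)
    if (is.na(k)) "" else k
  }, character(1), USE.NAMES = FALSE)
  ok <- nzchar(keys)
  out <- data.frame(smiles = products[ok], unique_key = keys[ok])
  out <- out[!duplicated(out$unique_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# H -> X: attach the target fragment at each heavy atom holding at least one
# implicit hydrogen.
apply_at_hydrogens <- function(g, tg) {
  hc <- implicit_h_counts(g)
  wc_t <- wildcard_indices(tg)
  if (length(wc_t) != 1L) return(character())
  vapply(which(hc >= 1L), function(at) {
    build_product(g, excise = integer(), stubs = c(`1` = at), tg)
  }, character(1))
}

apply_at_embeddings <- function(g, sg, tg) {
  wc_s <- wildcard_indices(sg)
  heavy_idx <- setdiff(seq_len(nrow(sg$atoms)), wc_s)
  if (!length(heavy_idx)) return(character())
  # attachment bookkeeping on the pattern's heavy-atom subgraph
  sub <- subgraph_atoms(sg, heavy_idx)
  patt <- sub$graph
  ap_labels <- lapply(seq_len(nrow(patt$atoms)), function(i) integer())
  for (w in wc_s) {
    b <- sg$bonds[sg$bonds$a1 == w | sg$bonds$a2 == w, ]
    ap <- setdiff(c(b$a1, b$a2), w)[[1L]]
    i <- sub$map[ap]
    ap_labels[[i]] <- c(ap_labels[[i]], sg$atoms$iso[w])
  }
  mc_g <- match_colors(g)
  mc_p <- match_colors(patt)
  vlev <- union(mc_g$vkey, mc_p$vkey)
  elev <- union(mc_g$ekey, mc_p$ekey)
  ig <- mol_igraph(g)
  ip <- mol_igraph(patt)
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(
      ip, ig, method = "vf2",
      vertex.color1 = match(mc_g$vkey, vlev),
      vertex.color2 = match(mc_p$vkey, vlev),
      edge.color1 = match(mc_g$ekey, elev),
      edge.color2 = match(mc_p$ekey, elev)),
    error = function(e) list())
  if (!length(maps)) return(character())
  acyclic <- acyclic_bond_indices(g)
  out <- character()
  for (mp in maps) {
    mapped <- as.integer(igraph::as_ids(mp))  # pattern vertex i -> atom mapped[i]
    M <- mapped
    in_M <- seq_len(nrow(g$atoms)) %in% M
    internal <- which(in_M[g$bonds$a1] & in_M[g$bonds$a2])
    if (length(internal) != nrow(patt$bonds)) next   # non-induced embedding
    external <- which(xor(in_M[g$bonds$a1], in_M[g$bonds$a2]))
    need <- vapply(ap_labels, length, integer(1))
    if (length(external) != sum(need)) next
    ok <- TRUE
    stub_options <- list()                 # per label: candidate stub atoms
    ext_at <- integer(nrow(g$atoms))
    for (e in external) {
      if (g$bonds$order[e] != 1L || !(e %in% acyclic)) { ok <- FALSE; break }
      m_end <- if (in_M[g$bonds$a1[e]]) g$bonds$a1[e] else g$bonds$a2[e]
      ext_at[m_end] <- ext_at[m_end] + 1L
    }
    if (!ok) next
    for (i in seq_along(mapped)) {
      if (ext_at[mapped[i]] != need[i]) { ok <- FALSE; break }
    }
    if (!ok) next
    # assign labels to stubs; when one attachment atom carries several
    # labels, enumerate the assignments
    assigns <- list(stats::setNames(integer(), character()))
    for (i in seq_along(mapped)) {
      labs <- ap_labels[[i]]
      if (!length(labs)) next
      exts <- external[vapply(external, function(e) {
        m_end <- if (in_M[g$bonds$a1[e]]) g$bonds$a1[e] else g$bonds$a2[e]
        m_end == mapped[i]
      }, logical(1))]
      stubs_here <- vapply(exts, function(e) {
        if (in_M[g$bonds$a1[e]]) g$bonds$a2[e] else g$bonds$a1[e]
      }, integer(1))
      new_assigns <- list()
      for (a in assigns) {
        for (p in perms_of(length(labs))) {
          a2 <- c(a, stats::setNames(stubs_here[p], as.character(labs)))
          new_assigns[[length(new_assigns) + 1L]] <- a2
        }
      }
      assigns <- new_assigns
    }
    for (a in assigns) {
      out <- c(out, build_product(g, excise = M, stubs = a, tg))
    }
  }
  out
}

# Remove `excise` atoms from g, insert the target fragment tg (minus its
# wildcards) and bond its attachment atoms to the stub atoms by label.
# Returns canonical SMILES or NA.
build_product <- function(g, excise, stubs, tg) {
  keep <- setdiff(seq_len(nrow(g$atoms)), excise)
  base <- subgraph_atoms(g, keep)
  pg <- base$graph
  wc_t <- wildcard_indices(tg)
  if (nrow(tg$atoms) - length(wc_t) == 0L) {
    # target is the hydrogen fragment: excision alone, implicit H restored
    if (!valence_ok(pg) || !graph_is_connected(pg)) return(NA_character_)
    return(smiles_from_mol(pg))
  }
  theavy <- subgraph_atoms(tg, setdiff(seq_len(nrow(tg$atoms)), wc_t))
  n0 <- nrow(pg$atoms)
  add_atoms <- theavy$graph$atoms
  add_atoms$iso <- 0L
  pg$atoms <- rbind(pg$atoms, add_atoms)
  if (nrow(theavy$graph$bonds)) {
    pg$bonds <- rbind(pg$bonds, data.frame(
      a1 = theavy$graph$bonds$a1 + n0, a2 = theavy$graph$bonds$a2 + n0,
      order = theavy$graph$bonds$order))
  }
  for (w in wc_t) {
    lab <- as.character(tg$atoms$iso[w])
    stub_old <- stubs[[lab]]
    if (is.null(stub_old) || is.na(stub_old)) return(NA_character_)
    b <- tg$bonds[tg$bonds$a1 == w | tg$bonds$a2 == w, ]
    ap <- setdiff(c(b$a1, b$a2), w)[[1L]]
    pg$bonds <- rbind(pg$bonds, data.frame(
      a1 = base$map[stub_old], a2 = theavy$map[ap] + n0, order = 1L))
  }
  if (!valence_ok(pg) || !graph_is_connected(pg)) return(NA_character_)
  smiles_from_mol(pg)
}

#' Optimization configuration
#'
#' @param direction `"decrease"`/`"increase"` for continuous endpoints,
#'   `"deactivate"`/`"activate"` for binary ones.
#' @param min_similarity Tanimoto threshold a product must reach against the
#'   starting molecule to be kept (default 0.5).
#' @param practical_threshold minimal practical effect a transformation must
#'   show to be applied: minimum `|mean_delta|` in log units for continuous
#'   endpoints (default 1.0), minimum deactivation (or activation) ratio for
#'   binary ones (default 0.55).
#' @param max_products_per_transformation cap on products taken from one
#'   transformation (default `Inf`).
#' @param radius,n_bits fingerprint parameters for the similarity filter.
#' @return a config list.
#' @export
optimization_config <- function(direction = c("decrease", "increase",
                                              "deactivate", "activate"),
                                min_similarity = 0.5,
                                practical_threshold = NULL,
                                max_products_per_transformation = Inf,
                                radius = 2L, n_bits = 2048L) {
  direction <- match.arg(direction)
  stopifnot(min_similarity >= 0, min_similarity <= 1)
  if (is.null(practical_threshold)) {
    practical_threshold <- if (direction %in% c("decrease", "increase"))
      1.0 else 0.55
  }
  list(direction = direction, min_similarity = min_similarity,
       practical_threshold = practical_threshold,
       max_products_per_transformation = max_products_per_transformation,
       radius = radius, n_bits = n_bits)
}

# Which (transformation, direction) applications serve the configured goal
# at the configured practical threshold.
select_applications <- function(stats, config) {
  rows <- list()
  for (i in seq_len(nrow(stats))) {
    if (!isTRUE(stats$significant[i])) next
    fwd <- bwd <- FALSE
    if (config$direction %in% c("decrease", "increase")) {
      md <- stats$mean_delta[i]
      if (is.na(md)) next
      want_neg <- config$direction == "decrease"
      if (abs(md) < config$practical_threshold) next
      fwd <- (md < 0) == want_neg
      bwd <- !fwd
    } else {
      want_deact <- config$direction == "deactivate"
      dr <- stats$deactivation_ratio[i]
      ar <- stats$activation_ratio[i]
      rev_dr <- if (!is.na(stats$npos_after[i]) && stats$npos_after[i] > 0)
        stats$n_activated[i] / stats$npos_after[i] else NA_real_
      rev_ar <- if (!is.na(stats$nneg_after[i]) && stats$nneg_after[i] > 0)
        stats$n_deactivated[i] / stats$nneg_after[i] else NA_real_
      fr <- if (want_deact) dr else ar
      br <- if (want_deact) rev_dr else rev_ar
      fwd <- !is.na(fr) && fr >= config$practical_threshold
      bwd <- !is.na(br) && br >= config$practical_threshold
    }
    if (fwd) rows[[length(rows) + 1L]] <- data.frame(i = i, direction = 1L)
    if (bwd) rows[[length(rows) + 1L]] <- data.frame(i = i, direction = -1L)
  }
  if (!length(rows)) return(data.frame(i = integer(), direction = integer()))
  do.call(rbind, rows)
}

#' Optimize a molecule with significant transformations
#'
#' Applies every significant transformation whose effect direction and
#' practical magnitude serve the configured goal, in the serving direction,
#' to the target molecule. Products are counted as `generated`, those within
#' the similarity filter as `kept`, and kept products whose predicted value
#' moves in the desired direction as `hits`; `effectiveness = hits / kept`
#' (reported `NA` when nothing is kept). Products on which the predictor
#' fails stay in `generated` but are excluded from `kept`.
#'
#' @param mol a single-row standardized molecule data.frame (or SMILES
#'   string).
#' @param stats transformation statistics from
#'   [significant_transformations()] (pre-filtering to `significant` rows is
#'   not required).
#' @param pred an `mmp_predictor` for the endpoint being optimized.
#' @param config an [optimization_config()].
#' @return object of class `mmp_optimization`: list with `products`
#'   (per-product rows) and `totals` (`generated`, `kept`, `hits`,
#'   `effectiveness`).
#' @export
optimize_molecule <- function(mol, stats, pred, config = optimization_config()) {
  if (is.character(mol)) mol <- standardize_molecules(mol)
  stopifnot(nrow(mol) == 1L, inherits(pred, "mmp_predictor"))
  apps <- select_applications(stats, config)
  fp0 <- fingerprint(mol$smiles, radius = config$radius,
                     n_bits = config$n_bits)
  orig <- predict_endpoint(pred, mol)
  rows <- list()
  for (r in seq_len(nrow(apps))) {
    i <- apps$i[r]; dir <- apps$direction[r]
    prods <- apply_transformation(mol$smiles, stats$left[i], stats$right[i],
                                  direction = dir)
    if (nrow(prods) > config$max_products_per_transformation) {
      prods <- prods[seq_len(config$max_products_per_transformation), ,
                     drop = FALSE]
    }
    if (!nrow(prods)) next
    prods$transformation <- stats$transformation[i]
    prods$direction <- dir
    rows[[length(rows) + 1L]] <- prods
  }
  if (!length(rows)) {
    products <- data.frame(smiles = character(), unique_key = character(),
                           transformation = character(),
                           direction = integer(), similarity = numeric(),
                           value_before = numeric(), value_after = numeric(),
                           kept = logical(), is_hit = logical())
    totals <- list(generated = 0L, kept = 0L, hits = 0L,
                   effectiveness = NA_real_)
    return(structure(list(molecule = mol, products = products,
                          totals = totals, config = config),
                     class = "mmp_optimization"))
  }
  products <- do.call(rbind, rows)
  products$similarity <- vapply(products$smiles, function(s) {
    tanimoto(fingerprint(s, radius = config$radius, n_bits = config$n_bits),
             fp0)
  }, numeric(1), USE.NAMES = FALSE)
  products$kept <- products$similarity >= config$min_similarity
  products$value_before <- if (pred$kind == "continuous")
    as.numeric(orig$value[1L]) else orig$value[1L]
  products$value_after <- NA
  products$is_hit <- FALSE
  kept_idx <- which(products$kept)
  if (length(kept_idx)) {
    pm <- data.frame(id = products$unique_key[kept_idx],
                     smiles = products$smiles[kept_idx],
                     unique_key = products$unique_key[kept_idx])
    res <- try(predict_endpoint(pred, pm), silent = TRUE)
    if (inherits(res, "try-error")) {
      res <- do.call(rbind, lapply(seq_len(nrow(pm)), function(j) {
        r <- try(predict_endpoint(pred, pm[j, , drop = FALSE]),
                 silent = TRUE)
        if (inherits(r, "try-error"))
          data.frame(value = NA, uncertainty = NA, in_domain = NA)
        else r
      }))
    }
    failed <- is.na(res$value)
    products$kept[kept_idx[failed]] <- FALSE
    okk <- kept_idx[!failed]
    products$value_after[okk] <- res$value[!failed]
    products$is_hit[okk] <- switch(
      config$direction,
      decrease = as.numeric(res$value[!failed]) < as.numeric(orig$value[1L]),
      increase = as.numeric(res$value[!failed]) > as.numeric(orig$value[1L]),
      deactivate = res$value[!failed] == "inactive",
      activate = res$value[!failed] == "active")
  }
  totals <- list(generated = nrow(products),
                 kept = sum(products$kept),
                 hits = sum(products$is_hit & products$kept))
  totals$effectiveness <- if (totals$kept > 0) totals$hits / totals$kept
                          else NA_real_
  rownames(products) <- NULL
  structure(list(molecule = mol, products = products, totals = totals,
                 config = config),
            class = "mmp_optimization")
}

#' @export
print.mmp_optimization <- function(x, ...) {
  eff <- if (is.na(x$totals$effectiveness)) "NA" else
    sprintf("%.0f%%", 100 * x$totals$effectiveness)
  cat("mmp_optimization of", x$molecule$id, "-", x$config$direction, "\n",
      "generated:", x$totals$generated,
      " kept:", x$totals$kept,
      " hits:", x$totals$hits,
      " effectiveness:", eff, "\n")
  invisible(x)
}
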