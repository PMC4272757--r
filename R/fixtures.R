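# Deterministic synthetic-library generator with planted transformation
# effects. The generator emulates a small combinatorial exploration: a set
# of decorated drug-like cores, each carrying one open substitution site,
# crossed with a vocabulary of small common substituents. The endpoint is
# additive - core baseline + substituent contribution + Gaussian noise - so
# the ground truth of every transformation's effect is known exactly.

#' Default substituent vocabulary
#'
#' Small common groups (hydrogen, methyl, hydroxyl, chloro, bromo, amino,
#' carboxyl) as single-attachment fragment notations.
#' @return named character vector.
#' @export
mmp_substituent_vocabulary <- function() {
  c(H = "[*:1][H]",
    methyl = "[*:1]C",
    hydroxyl = "[*:1]O",
    chloro = "[*:1]Cl",
    bromo = "[*:1]Br",
    amino = "[*:1]N",
    carboxyl = "[*:1]C(=O)O")
}

# Decorated cores, each with one open aromatic substitution site. Cores are
# large enough (12-16 heavy atoms) that two same-core molecules differing in
# one small substituent stay above the default 50% Tanimoto pair filter.
mmp_fixture_cores <- function() {
  c("[*:1]c1ccc(CCNC(C)=O)cc1",
    "[*:1]c1ccc(OCC(=O)NC)cc1",
    "[*:1]c1ccc(CN2CCOCC2)cc1",
    "[*:1]c1ccc(C(=O)NCc2ccccc2)cc1",
    "[*:1]c1ccc(CCNC(=O)c2ccncc2)cc1",
    "[*:1]c1ccc(OCCN(C)C)cc1",
    "[*:1]c1ccc(NC(=O)c2ccco2)cc1",
    "[*:1]c1ccc(CC(=O)N2CCCC2)cc1",
    "[*:1]c1ccc(-c2ccccc2OC)cc1",
    "[*:1]c1ccc(CNC(=O)CCC)cc1",
    "[*:1]c1ccc(OCc2ccccn2)cc1",
    "[*:1]c1ccc(N2CCN(C)CC2)cc1")
}

#' Describe a planted transformation effect
#'
#' @param left,right single-attachment fragment notations.
#' @param effect endpoint shift (log units) when `right` replaces `left`.
#' @return a `planted_effect` list.
#' @export
planted_effect <- function(left, right, effect) {
  stopifnot(is.finite(effect))
  structure(list(left = canonical_fragment(left)$notation,
                 right = canonical_fragment(right)$notation,
                 effect = effect),
            class = "planted_effect")
}

# Resolve planted effects into per-fragment additive contributions
# (unmentioned fragments contribute 0; left fragments anchor at 0 unless
# already assigned).
resolve_contributions <- function(vocabulary, effects) {
  contrib <- stats::setNames(rep(0, length(vocabulary)),
                             unname(vocabulary))
  for (ef in effects) {
    if (!ef$left %in% names(contrib) || !ef$right %in% names(contrib)) {
      stop("planted effect refers to fragments outside the vocabulary: ",
           ef$left, " >> ", ef$right)
    }
    contrib[ef$right] <- contrib[ef$left] + ef$effect
  }
  contrib
}

#' Generate a synthetic compound library with planted effects
#'
#' Builds the cross product of `n_scaffolds` decorated cores with the
#' substituent vocabulary, assigns each molecule the endpoint value
#' `base(core) + contribution(substituent) + N(0, noise_sd)`, and emits an
#' endpoint table with experimental rows (for a seeded `exp_fraction` subset
#' of molecules) and, optionally, predicted rows for every molecule with
#' noise `pred_noise_sd` reported as the prediction uncertainty. A binary
#' companion endpoint (`<endpoint>_class`) is derived by thresholding the
#' continuous value. Output is byte-identical for identical seeds.
#'
#' @param seed integer RNG seed.
#' @param n_scaffolds number of cores (max `length(mmp_fixture_cores())`).
#' @param substituents named substituent vocabulary (fragment notations).
#' @param effects list of [planted_effect()]s (or a named numeric vector of
#'   per-fragment contributions).
#' @param noise_sd experimental noise standard deviation (log units).
#' @param base_range range of core baselines, drawn uniformly per core.
#' @param exp_fraction fraction of molecules receiving an experimental row.
#' @param predicted also emit predicted rows for every molecule.
#' @param pred_noise_sd prediction noise / reported uncertainty.
#' @param binary_threshold threshold for the binary companion endpoint
#'   (default: midpoint of `base_range` plus half the largest planted
#'   contribution).
#' @param endpoint endpoint name (default `"activity"`).
#' @return object of class `mmp_library`: list with `molecules` (standardized
#'   data.frame), `endpoints`, `contributions`, `cores`, `substituents`,
#'   `seed`.
#' @export
generate_library <- function(seed = 42L, n_scaffolds = 10L,
                             substituents = mmp_substituent_vocabulary(),
                             effects = list(
                               planted_effect("[*:1]C", "[*:1]O", 1.0)),
                             noise_sd = 0.1,
                             base_range = c(4, 6),
                             exp_fraction = 1.0,
                             predicted = FALSE,
                             pred_noise_sd = 0.3,
                             binary_threshold = NULL,
                             endpoint = "activity") {
  cores <- mmp_fixture_cores()
  if (n_scaffolds > length(cores)) {
    stop("at most ", length(cores), " cores available")
  }
  cores <- cores[seq_len(n_scaffolds)]
  if (is.numeric(effects)) {
    contrib <- stats::setNames(rep(0, length(substituents)),
                               unname(substituents))
    contrib[names(effects)] <- effects
  } else {
    contrib <- resolve_contributions(substituents, effects)
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  base <- stats::runif(n_scaffolds, base_range[1L], base_range[2L])
  grid <- expand.grid(core = seq_len(n_scaffolds),
                      sub = seq_along(substituents))
  smiles <- character(nrow(grid))
  ids <- character(nrow(grid))
  true_value <- numeric(nrow(grid))
  keep <- logical(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    ci <- grid$core[r]; si <- grid$sub[r]
    smi <- try(reassemble_fragments(cores[ci], substituents[[si]]),
               silent = TRUE)
    if (inherits(smi, "try-error") || is.na(smi)) {
      warning("invalid core/substituent combination skipped: core ", ci,
              " + ", names(substituents)[si])
      next
    }
    keep[r] <- TRUE
    smiles[r] <- smi
    ids[r] <- paste0("S", formatC(ci, width = 2, flag = "0"), "_",
                     names(substituents)[si])
    true_value[r] <- base[ci] + contrib[[substituents[[si]]]]
  }
  smiles <- smiles[keep]; ids <- ids[keep]; true_value <- true_value[keep]
  mols <- standardize_molecules(smiles, id = ids)
  if (is.null(binary_threshold)) {
    binary_threshold <- mean(base_range) + max(c(contrib, 0)) / 2
  }
  n <- nrow(mols)
  exp_sel <- stats::runif(n) <= exp_fraction
  exp_value <- true_value + stats::rnorm(n, 0, noise_sd)
  rows <- list()
  if (any(exp_sel)) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = mols$id[exp_sel], endpoint = endpoint, kind = "continuous",
      value = as.character(exp_value[exp_sel]), source = "experimental",
      uncertainty = 0, in_domain = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      id = mols$id[exp_sel], endpoint = paste0(endpoint, "_class"),
      kind = "binary",
      value = ifelse(exp_value[exp_sel] > binary_threshold,
                     "active", "inactive"),
      source = "experimental", uncertainty = 0, in_domain = TRUE)
  }
  if (predicted) {
    pred_value <- true_value + stats::rnorm(n, 0, pred_noise_sd)
    mis <- if (pred_noise_sd > 0)
      stats::pnorm(-abs(pred_value - binary_threshold) / pred_noise_sd)
      else rep(0, n)
    rows[[length(rows) + 1L]] <- data.frame(
      id = mols$id, endpoint = endpoint, kind = "continuous",
      value = as.character(pred_value), source = "predicted",
      uncertainty = pred_noise_sd, in_domain = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      id = mols$id, endpoint = paste0(endpoint, "_class"), kind = "binary",
      value = ifelse(pred_value > binary_threshold, "active", "inactive"),
      source = "predicted", uncertainty = pmin(mis, 0.5), in_domain = TRUE)
  }
  endpoints <- normalize_endpoints(do.call(rbind, rows))
  structure(list(molecules = mols, endpoints = endpoints,
                 contributions = contrib, cores = cores,
                 substituents = substituents, seed = seed,
                 binary_threshold = binary_threshold,
                 endpoint = endpoint),
            class = "mmp_library")
}

#' @export
print.mmp_library <- function(x, ...) {
  cat("mmp_library:", nrow(x$molecules), "molecules over",
      length(x$cores), "cores x", length(x$substituents),
      "substituents; endpoint:", x$endpoint, "\n")
  invisible(x)
}

#' Write a synthetic library to disk
#'
#' Emits the same formats the readers consume: a SMILES file
#' (`molecules.smi`) and a tab-separated endpoint table (`endpoints.tsv`).
#' @param lib an `mmp_library`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_smiles_file(lib$molecules, file.path(dir, "molecules.smi"))
  write_endpoint_table(lib$endpoints, file.path(dir, "endpoints.tsv"))
  invisible(dir)
}
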