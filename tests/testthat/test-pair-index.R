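toluene_phenol_index <- function(extra = character(), ids = NULL,
                                 max_cuts = 1L) {
  smi <- c("Cc1ccccc1", "Oc1ccccc1", extra)
  if (is.null(ids)) ids <- paste0("m", seq_along(smi))
  mols <- standardize_molecules(smi, id = ids)
  suppressWarnings(build_index(mols, max_cuts = max_cuts))
}

test_that("the index is keyed by scaffold and unique structure", {
  idx <- toluene_phenol_index()
  shared <- idx$fragmentations[idx$fragmentations$scaffold ==
                                 "[*:1]c1ccccc1", ]
  expect_setequal(shared$variable, c("[*:1]C", "[*:1]O"))
  expect_setequal(shared$mol_id, c("m1", "m2"))
  # duplicate structures are indexed once and aliased
  dup <- standardize_molecules(c("Cc1ccccc1", "c1ccccc1C"),
                               id = c("t1", "t2"))
  idx2 <- suppressWarnings(build_index(dup, max_cuts = 1L))
  expect_equal(nrow(idx2$molecules), 1L)
  expect_equal(idx2$aliases$id, "t2")
  expect_equal(idx2$aliases$canonical_id, "t1")
  # duplicate ids are an error
  expect_error(build_index(data.frame(id = c("a", "a"),
                                      smiles = c("C", "CC"),
                                      unique_key = c("k1", "k2"))),
               "duplicate molecule ids")
})

test_that("matched pairs require a shared scaffold and pass the filter", {
  idx <- toluene_phenol_index()
  pairs <- find_matched_pairs(idx, min_similarity = 0)
  expect_equal(length(unique(pairs$pair_group)), 1L)
  expect_setequal(c(pairs$frag_a, pairs$frag_b), c("[*:1]C", "[*:1]O"))
  # a perfect-similarity threshold excludes distinct molecules
  expect_equal(nrow(find_matched_pairs(idx, min_similarity = 1.0)), 0L)
  # single molecule: nothing to pair
  solo <- suppressWarnings(build_index(standardize_molecules("Cc1ccccc1"),
                                       max_cuts = 1L))
  expect_equal(nrow(find_matched_pairs(solo, min_similarity = 0)), 0L)
})

test_that("three analogues give all three pair groups on the shared core", {
  idx <- toluene_phenol_index(extra = "Nc1ccccc1")
  pairs <- find_matched_pairs(idx, min_similarity = 0)
  expect_equal(length(unique(pairs$pair_group)), choose(3, 2))
})

test_that("pair extraction is invariant to molecule input order", {
  smi <- c("Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "Clc1ccccc1")
  ids <- paste0("m", 1:4)
  key <- function(ord) {
    mols <- standardize_molecules(smi[ord], id = ids[ord])
    idx <- suppressWarnings(build_index(mols, max_cuts = 1L))
    p <- find_matched_pairs(idx, min_similarity = 0)
    sort(paste(p$mol_a, p$mol_b, p$scaffold, p$frag_a, p$frag_b))
  }
  expect_identical(key(1:4), key(c(3, 1, 4, 2)))
})

test_that("transformations group pairs canonically and conserve multiplicity", {
  # four different scaffolds all realizing the H -> Cl replacement
  smi <- c("c1ccccc1", "Clc1ccccc1",
           "c1ccc2ccccc2c1", "Clc1ccc2ccccc2c1",
           "CC(C)C", "CC(C)CCl",
           "C1CCCCC1", "ClC1CCCCC1")
  mols <- standardize_molecules(smi, id = paste0("m", seq_along(smi)))
  idx <- suppressWarnings(build_index(mols, max_cuts = 1L))
  pairs <- find_matched_pairs(idx, min_similarity = 0)
  tx <- extract_transformations(pairs)
  hcl <- tx$transformations[tx$transformations$left == "[*:1]Cl" &
                              tx$transformations$right == "[*:1][H]", ]
  expect_equal(nrow(hcl), 1L)
  expect_gte(hcl$n_pairs, 4L)
  # conservation: every pair is assigned to exactly one transformation
  expect_equal(sum(tx$transformations$n_pairs), nrow(tx$pairs))
  expect_false(any(is.na(tx$pairs$transformation)))
})

test_that("opposite orientations of one replacement collapse with signs", {
  idx <- toluene_phenol_index(ids = c("zz_toluene", "aa_phenol"))
  pairs <- find_matched_pairs(idx, min_similarity = 0)
  tx <- extract_transformations(pairs)
  tf <- tx$transformations
  expect_equal(nrow(tf), 1L)
  expect_true(tf$left <= tf$right)  # canonical orientation
  expect_equal(tf$left, "[*:1]C")
  # mol_a = aa_phenol sorts first, so the realized change O -> C runs
  # right -> left and must carry sign -1
  expect_equal(tx$pairs$sign, -1L)
})

test_that("pair deltas prefer experimental values and respect the domain", {
  idx <- toluene_phenol_index()
  pairs <- find_matched_pairs(idx, min_similarity = 0)
  ep <- normalize_endpoints(data.frame(
    id = c("m1", "m2", "m1", "m2"), endpoint = "act", kind = "continuous",
    value = c("5", "6", "4", "9"),
    source = c("experimental", "predicted", "predicted", "experimental"),
    uncertainty = c(0, 0.5, 0.4, 0), in_domain = TRUE))
  pd <- pair_deltas(pairs, ep, "act")
  # experimental values 5 (m1) and 9 (m2) win over the predicted copies
  expect_equal(pd$value_a, 5)
  expect_equal(pd$value_b, 9)
  expect_equal(pd$delta, 4)
  expect_equal(pd$provenance, "experimental")
  expect_equal(pd$uncertainty, 0)
  # an out-of-domain prediction drops the pair unless explicitly included
  ep2 <- normalize_endpoints(data.frame(
    id = c("m1", "m2"), endpoint = "act", kind = "continuous",
    value = c("5", "6"), source = c("experimental", "predicted"),
    uncertainty = c(0, 0.5), in_domain = c(TRUE, FALSE)))
  expect_equal(nrow(pair_deltas(pairs, ep2, "act")), 0L)
  kept <- pair_deltas(pairs, ep2, "act", include_out_of_domain = TRUE)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$provenance, "predicted")
  expect_error(pair_deltas(pairs, ep, "missing"), "no endpoint rows")
})

test_that("pairs reassemble to their member molecules", {
  idx <- toluene_phenol_index(extra = "Nc1ccccc1", max_cuts = 2L)
  pairs <- find_matched_pairs(idx, min_similarity = 0)
  mols <- idx$molecules
  for (i in seq_len(nrow(pairs))) {
    expect_equal(reassemble_fragments(pairs$scaffold[i], pairs$frag_a[i]),
                 mols$smiles[mols$id == pairs$mol_a[i]])
    expect_equal(reassemble_fragments(pairs$scaffold[i], pairs$frag_b[i]),
                 mols$smiles[mols$id == pairs$mol_b[i]])
  }
})
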