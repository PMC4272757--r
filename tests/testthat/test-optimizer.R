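test_that("applying a transformation rewrites every severable embedding", {
  p <- apply_transformation("Cc1ccccc1", "[*:1]C", "[*:1]O", 1L)
  expect_equal(p$smiles, "Oc1ccccc1")
  # reverse direction inverts the replacement
  p2 <- apply_transformation("Oc1ccccc1", "[*:1]C", "[*:1]O", -1L)
  expect_equal(p2$smiles, "Cc1ccccc1")
  # symmetry-equivalent sites collapse after canonicalization
  p3 <- apply_transformation("Cc1ccc(C)cc1", "[*:1]C", "[*:1]O", 1L)
  expect_equal(nrow(p3), 1L)
  # no embedding: empty result, not an error
  p4 <- apply_transformation("c1ccccc1", "[*:1]C", "[*:1]O", 1L)
  expect_equal(nrow(p4), 0L)
})

test_that("hydrogen replacements work in both directions", {
  p <- apply_transformation("c1ccccc1", "[*:1][H]", "[*:1]Cl", 1L)
  expect_equal(p$smiles, "Clc1ccccc1")
  back <- apply_transformation(p$smiles, "[*:1]Cl", "[*:1][H]", 1L)
  expect_equal(back$smiles, "c1ccccc1")
  # toluene has two symmetry-distinct kinds of ring H plus the methyl H
  pt <- apply_transformation("Cc1ccccc1", "[*:1][H]", "[*:1]O", 1L)
  expect_equal(nrow(pt), 4L)
})

test_that("round trip through a transformation recovers the original key", {
  for (smi in c("Cc1ccccc1", "CC(=O)NCCc1ccc(C)cc1", "Cc1ccco1")) {
    orig <- standardize_molecules(smi)
    fwd <- apply_transformation(orig$smiles, "[*:1]C", "[*:1]O", 1L)
    expect_gt(nrow(fwd), 0L)
    keys <- unlist(lapply(fwd$smiles, function(s) {
      apply_transformation(s, "[*:1]C", "[*:1]O", -1L)$unique_key
    }))
    expect_true(orig$unique_key %in% keys)
  }
})

test_that("embeddings respect the attachment environment", {
  # a linker pattern must not match inside a ring
  p <- apply_transformation("C1OCCCC1", "[*:2]O[*:1]", "[*:2]C[*:1]", 1L)
  expect_equal(nrow(p), 0L)
  # an aromatic fragment must not match a saturated ring
  p2 <- apply_transformation("CC1CCCCC1", "[*:1]c1ccccc1", "[*:1]O", 1L)
  expect_equal(nrow(p2), 0L)
  # but it does match a genuine aromatic context regardless of kekulization
  p3 <- apply_transformation("c1ccc(-c2ccccc2)cc1", "[*:1]c1ccccc1",
                             "[*:1]O", 1L)
  expect_equal(p3$smiles, "Oc1ccccc1")
  # linker replacement in an acyclic context works
  p4 <- apply_transformation("CCOc1ccccc1", "[*:2]O[*:1]", "[*:2]C[*:1]",
                             1L)
  expect_equal(p4$smiles, "CCCc1ccccc1")
})

test_that("valence-impossible products are discarded", {
  # F carries one bond; attaching a second substituent is impossible, so a
  # transformation whose source matches at fluorine's neighbour must not
  # produce a pentavalent carbon
  p <- apply_transformation("FC(F)(F)CF", "[*:1][H]", "[*:1]O", 1L)
  for (s in p$smiles) {
    g <- mmpamp:::mol_from_smiles(s)
    expect_true(mmpamp:::valence_ok(g))
  }
})

test_that("optimization counts generated, kept and hits consistently", {
  lib <- fixture_library()
  res <- fixture_analysis()
  pred <- toy_additive_predictor(lib$contributions, intercept = 5,
                                 noise_sd = 0, endpoint = "activity")
  target <- lib$molecules[lib$molecules$id == "S01_methyl", ]
  opt <- suppressWarnings(
    optimize_molecule(target, res$stats, pred,
                      optimization_config(direction = "increase")))
  expect_gt(opt$totals$generated, 0L)
  expect_lte(opt$totals$kept, opt$totals$generated)
  expect_lte(opt$totals$hits, opt$totals$kept)
  expect_true(all(opt$products$similarity[opt$products$kept] >= 0.5))
  # with the zero-noise predictor every beneficial product is a hit
  expect_equal(opt$totals$effectiveness, 1.0)
  # the practical-threshold filter excludes weak transformations: only the
  # planted +1.0 hydroxyl effects are applied, in the increasing direction
  expect_true(all(opt$products$direction == 1L |
                    opt$products$transformation %in%
                      res$stats$transformation))
})

test_that("raising the similarity filter never increases kept or hits", {
  lib <- fixture_library()
  res <- fixture_analysis()
  pred <- toy_additive_predictor(lib$contributions, intercept = 5,
                                 noise_sd = 0, endpoint = "activity")
  target <- lib$molecules[lib$molecules$id == "S01_methyl", ]
  prev_kept <- Inf; prev_hits <- Inf
  for (ms in c(0.3, 0.6, 1.0)) {
    opt <- suppressWarnings(
      optimize_molecule(target, res$stats, pred,
                        optimization_config(direction = "increase",
                                            min_similarity = ms)))
    expect_lte(opt$totals$kept, prev_kept)
    expect_lte(opt$totals$hits, prev_hits)
    prev_kept <- opt$totals$kept; prev_hits <- opt$totals$hits
  }
  # the boundary case: nothing survives a perfect-identity filter
  expect_equal(prev_kept, 0L)
})

test_that("hit accounting follows the predictor, not the transformation", {
  lib <- fixture_library()
  res <- fixture_analysis()
  pred <- toy_additive_predictor(lib$contributions, intercept = 5,
                                 noise_sd = 0, endpoint = "activity")
  # ask for a decrease: the planted effects all increase the endpoint, so
  # the engine applies them in reverse (hydroxyl removal)
  target <- lib$molecules[lib$molecules$id == "S01_hydroxyl", ]
  opt <- suppressWarnings(
    optimize_molecule(target, res$stats, pred,
                      optimization_config(direction = "decrease")))
  expect_gt(opt$totals$kept, 0L)
  # the carboxyl replacement keeps an embedded hydroxyl fragment, which the
  # additive predictor honestly scores; every other replacement is a hit
  prods <- opt$products[opt$products$kept, ]
  cooh <- grepl("C(=O)O", prods$smiles, fixed = TRUE) |
    grepl("OC(=O)", prods$smiles, fixed = TRUE)
  expect_true(all(prods$is_hit[!cooh]))
  expect_false(any(prods$is_hit[cooh]))
  expect_equal(opt$totals$effectiveness,
               sum(prods$is_hit) / nrow(prods))
})

test_that("optimization config validates its inputs", {
  expect_error(optimization_config(min_similarity = 1.2))
  cfg <- optimization_config("deactivate")
  expect_equal(cfg$practical_threshold, 0.55)
  cfg2 <- optimization_config("decrease")
  expect_equal(cfg2$practical_threshold, 1.0)
})
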