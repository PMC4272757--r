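# Shared fixtures, built once per test session and cached on disk so the
# expensive fragmentation/index stage is not repeated across test files.

fixture_cache_path <- function(name) {
  file.path(tempdir(), paste0("mmpamp-cache-", name, ".rds"))
}

with_fixture_cache <- function(name, builder) {
  path <- fixture_cache_path(name)
  if (file.exists(path)) return(readRDS(path))
  obj <- builder()
  saveRDS(obj, path)
  obj
}

# The reference synthetic library: 10 cores x 7 substituents, planted
# methyl -> hydroxyl effect of +1.0 log units, experimental noise 0.1.
fixture_library <- function() {
  with_fixture_cache("library42", function() {
    suppressWarnings(generate_library(seed = 42L))
  })
}

# Full analysis of the reference library under default settings.
fixture_analysis <- function() {
  with_fixture_cache("analysis42", function() {
    lib <- fixture_library()
    dir <- tempfile("mmp-fixture-out")
    cfg <- mmp_config(out_dir = dir, seed = 7L, endpoint = "activity")
    suppressWarnings(run_pipeline(cfg, molecules = lib$molecules,
                                  endpoints = lib$endpoints))
  })
}

# A small synthetic transformation/pair/endpoint trio with every pair
# concordant (+1 delta); used by the amplification and bootstrap tests.
synthetic_evidence <- function(n_exp, n_pred, uncertainty,
                               endpoint = "act") {
  n <- n_exp + n_pred
  src <- c(rep("experimental", n_exp), rep("predicted", n_pred))
  pairs <- data.frame(
    mol_a = paste0("a", seq_len(n)), mol_b = paste0("b", seq_len(n)),
    scaffold = "s", frag_a = "[*:1]C", frag_b = "[*:1]O", n_cuts = 1L,
    similarity = 1, pair_group = paste0("g", seq_len(n)),
    transformation = "T0001", sign = 1L)
  ep <- rbind(
    data.frame(id = pairs$mol_a, endpoint = endpoint, kind = "continuous",
               value = "5", source = src,
               uncertainty = ifelse(src == "predicted", uncertainty, 0),
               in_domain = TRUE),
    data.frame(id = pairs$mol_b, endpoint = endpoint, kind = "continuous",
               value = "6", source = src,
               uncertainty = ifelse(src == "predicted", uncertainty, 0),
               in_domain = TRUE))
  list(transformations = data.frame(transformation = "T0001",
                                    left = "[*:1]C", right = "[*:1]O",
                                    n_cuts = 1L, n_pairs = n),
       pairs = pairs,
       endpoints = normalize_endpoints(ep))
}

# Independent exact-count oracle for the binomial lower tail: Pascal's
# triangle in plain integer arithmetic (no dbinom/choose/pbinom).
oracle_binom_lower_tail <- function(m, n) {
  row <- 1
  for (i in seq_len(n)) row <- c(0, row) + c(row, 0)
  sum(row[seq_len(m + 1L)]) / 2^n
}

# Literal exhaustive enumeration over all 2^n sign vectors (small n).
oracle_enumeration <- function(m, n) {
  outcomes <- 0L
  total <- 2^n
  for (x in 0:(total - 1L)) {
    ones <- sum(bitwAnd(bitwShiftR(x, 0:(n - 1L)), 1L))
    if (ones <= m) outcomes <- outcomes + 1L
  }
  outcomes / total
}

# Hand-rolled step-down Holm procedure (oracle for holm_bonferroni).
oracle_holm <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha / (m - k + 1)) reject[ord[k]] <- TRUE
    else break
  }
  reject
}

skip_noise <- function(expr) suppressWarnings(expr)
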