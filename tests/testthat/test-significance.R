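test_that("the regression p-value equals its exact enumeration oracle", {
  # frozen hand-derived values
  expect_equal(pvalue_regression(2, 2), 11 / 16)
  expect_equal(pvalue_regression(0, 10), 0.5^10)
  expect_equal(pvalue_regression(0, 1), 0.5)
  expect_error(pvalue_regression(0, 0), "N = 0")
  # literal 2^N enumeration for small N
  for (n in c(3L, 6L, 9L)) {
    for (np in 0:n) {
      expect_equal(pvalue_regression(np, n - np),
                   oracle_enumeration(min(np, n - np), n),
                   tolerance = 1e-12)
    }
  }
  # Pascal-count oracle further out
  for (n in c(12L, 15L)) {
    for (np in 0:n) {
      expect_equal(pvalue_regression(np, n - np),
                   oracle_binom_lower_tail(min(np, n - np), n),
                   tolerance = 1e-12)
    }
  }
})

test_that("the regression p-value is symmetric and monotone in the minority", {
  for (n in c(5L, 11L, 18L)) {
    ps <- vapply(0:n, function(np) pvalue_regression(np, n - np), numeric(1))
    expect_equal(ps, rev(ps))                       # symmetry
    half <- ps[seq_len(floor(n / 2) + 1L)]
    expect_true(all(diff(half) >= 0))               # monotone in min count
  }
})

test_that("the classification p-value matches the printed two-tail minimum", {
  expect_equal(pvalue_classification(10, 0, 10, 0), 1.0)
  expect_equal(pvalue_classification(5, 5, 0, 10), 0.5^10)
  expect_equal(pvalue_classification(3, 1, 1, 3), 0.05078125)
  expect_error(pvalue_classification(3, 1, 1, 2), "totals differ")
  # degenerate rates use point masses; the impossible-under-null all-flip
  # case is floored to keep the log level finite
  expect_equal(pvalue_classification(0, 4, 0, 4), 1.0)
  expect_equal(pvalue_classification(4, 0, 0, 4), .Machine$double.xmin)
})

test_that("significance level is the negative decadic log", {
  expect_equal(significance_level(0.01), 2)
  expect_equal(significance_level(0.001), 3)
  expect_equal(significance_level(1.0), 0)
  expect_error(significance_level(0), "\\(0, 1\\]")
  expect_error(significance_level(1.5), "\\(0, 1\\]")
})

test_that("holm correction reproduces the step-down oracle", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03), 0.05),
               c(TRUE, FALSE, FALSE))
  expect_equal(holm_bonferroni(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(holm_bonferroni(0.04, 0.05), TRUE)
  expect_equal(holm_bonferroni(numeric(), 0.05), logical())
  set.seed(11)
  for (r in 1:50) {
    p <- stats::runif(sample(1:12, 1))^sample(1:3, 1)
    got <- holm_bonferroni(p, 0.05)
    expect_identical(got, oracle_holm(p, 0.05))
    # Holm rejects a superset of plain Bonferroni
    bonf <- p <= 0.05 / length(p)
    expect_true(all(got[bonf]))
  }
})

test_that("bootstrap p-values respond to prediction uncertainty", {
  base <- data.frame(kind = "continuous", value_a = rep(5, 50),
                     value_b = rep(6, 50), source_a = "predicted",
                     source_b = "predicted", unc_a = 0.1, unc_b = 0.1,
                     sign = 1L)
  tight <- bootstrap_significance(base, n_replicas = 200L, seed = 5L)
  expect_lt(tight$bootstrap_p, 1e-6)   # effect robust to small noise
  loose <- base; loose$unc_a <- 10; loose$unc_b <- 10
  washed <- bootstrap_significance(loose, n_replicas = 200L, seed = 5L)
  expect_gt(washed$bootstrap_p, 0.05)  # sign flips approach a coin toss
  # zero uncertainty degenerates to the unperturbed p-value, any seed
  exact <- base; exact$unc_a <- 0; exact$unc_b <- 0
  for (s in c(1L, 99L)) {
    expect_equal(bootstrap_significance(exact, 20L, seed = s)$bootstrap_p,
                 pvalue_regression(50, 0))
  }
  # reproducible bit-for-bit from the seed
  a <- bootstrap_significance(base, 100L, seed = 3L)
  b <- bootstrap_significance(base, 100L, seed = 3L)
  expect_identical(a$replica_p, b$replica_p)
  # missing uncertainty on a predicted value is an error
  bad <- base; bad$unc_a <- NA_real_
  expect_error(bootstrap_significance(bad, 10L, seed = 1L), "uncertainty")
})

test_that("binary bootstrap flips labels at the stated probability", {
  d <- data.frame(kind = "binary", value_a = rep("active", 30),
                  value_b = rep("inactive", 30), source_a = "predicted",
                  source_b = "predicted", unc_a = 0, unc_b = 0, sign = 1L)
  crisp <- bootstrap_significance(d, 50L, seed = 2L)
  expect_equal(crisp$bootstrap_p, pvalue_classification(30, 0, 0, 30))
  noisy <- d; noisy$unc_a <- 0.5; noisy$unc_b <- 0.5
  washed <- bootstrap_significance(noisy, 200L, seed = 2L)
  expect_gt(washed$bootstrap_p, 0.05)
})

test_that("transformation statistics honour the pair-count threshold", {
  ev <- synthetic_evidence(3, 0, 0)
  st <- significant_transformations(ev$transformations, ev$pairs,
                                    ev$endpoints, "act")
  expect_false(st$tested)
  expect_true(is.na(st$p_value))
  expect_false(st$significant)
  ev5 <- synthetic_evidence(5, 0, 0)
  st5 <- significant_transformations(ev5$transformations, ev5$pairs,
                                     ev5$endpoints, "act")
  expect_true(st5$tested)
  expect_equal(st5$p_value, 0.5^5)
  expect_equal(st5$significance_level, -log10(st5$p_value))
  expect_equal(st5$n_pos, 5L)
  expect_equal(st5$mean_delta, 1)
})

test_that("zero-delta pairs are excluded from the direction counts", {
  ev <- synthetic_evidence(6, 0, 0)
  ep <- ev$endpoints
  # make two pairs exact ties
  ep$value[ep$id %in% c("b1", "b2")] <- "5"
  st <- significant_transformations(ev$transformations, ev$pairs, ep, "act")
  expect_equal(st$n_zero, 2L)
  expect_equal(st$n_pos, 4L)
  expect_equal(st$N, st$n_pos + st$n_neg + st$n_zero)
  expect_equal(st$p_value, pvalue_regression(4, 0))
})

test_that("binary endpoint statistics count label transitions", {
  n <- 8L
  pairs <- data.frame(mol_a = paste0("a", 1:n), mol_b = paste0("b", 1:n),
                      scaffold = "s", frag_a = "[*:1]C", frag_b = "[*:1]O",
                      n_cuts = 1L, similarity = 1,
                      pair_group = paste0("g", 1:n),
                      transformation = "T0001", sign = 1L)
  before <- c(rep("active", 6), rep("inactive", 2))
  after <- c(rep("inactive", 6), rep("inactive", 2))
  ep <- normalize_endpoints(rbind(
    data.frame(id = pairs$mol_a, endpoint = "cls", kind = "binary",
               value = before, source = "experimental", uncertainty = 0,
               in_domain = TRUE),
    data.frame(id = pairs$mol_b, endpoint = "cls", kind = "binary",
               value = after, source = "experimental", uncertainty = 0,
               in_domain = TRUE)))
  tf <- data.frame(transformation = "T0001", left = "[*:1]C",
                   right = "[*:1]O", n_cuts = 1L, n_pairs = n)
  st <- significant_transformations(tf, pairs, ep, "cls")
  expect_equal(st$n_pos, 6L)            # actives before
  expect_equal(st$npos_after, 0L)
  expect_equal(st$n_deactivated, 6L)
  expect_equal(st$deactivation_ratio, 1)
  expect_equal(st$p_value, pvalue_classification(6, 2, 0, 8))
  expect_equal(st$n_pos + st$n_neg, st$npos_after + st$nneg_after)
})

test_that("a mixed-kind endpoint is rejected", {
  ev <- synthetic_evidence(5, 0, 0)
  ep <- ev$endpoints
  ep$kind[1] <- "binary"
  expect_error(significant_transformations(ev$transformations, ev$pairs,
                                           ep, "act"),
               "kind inconsistent")
})
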