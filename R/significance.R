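# Binomial significance tests for transformations, Holm-Bonferroni
# correction, and the applicability-domain bootstrap.

#' Exact binomial sign-test p-value for a continuous endpoint
#'
#' Probability that a symmetric binomial variable falls at or below the
#' smaller of the two direction counts:
#' `P[Bin(N, 0.5) <= min(n_pos, n_neg)]` with `N = n_pos + n_neg`.
#' Computed by exact summation of binomial terms; no normal approximation.
#'
#' @param n_pos pairs that increased the property (canonical direction).
#' @param n_neg pairs that decreased it.
#' @return p-value in (0, 1].
#' @export
pvalue_regression <- function(n_pos, n_neg) {
  stopifnot(length(n_pos) == 1L, length(n_neg) == 1L,
            n_pos >= 0, n_neg >= 0)
  n <- n_pos + n_neg
  if (n < 1L) stop("no pairs: N = 0")
  if (n > 10000L) stop("N above exact-summation cap (10,000)")
  binom_lower_tail(min(n_pos, n_neg), n, 0.5)
}

# Exact lower tail by term summation; p = 0 and p = 1 degenerate to point
# masses.
binom_lower_tail <- function(x, n, p) {
  x <- floor(x)
  if (x >= n) return(1.0)
  if (p <= 0) return(1.0)               # point mass at 0 <= x for x >= 0
  if (p >= 1) return(if (x >= n) 1.0 else 0.0)
  sum(stats::dbinom(0:x, n, p))
}

#' Exact binomial p-value for a binary endpoint
#'
#' For a classification property the transformation is tested against the
#' "no effect" binomial null: with `n_pos`/`n_neg` actives/inactives before
#' the transformation and `npos_after`/`nneg_after` after, the p-value is
#' `min( P[Bin(N, n_pos/N) <= npos_after], P[Bin(N, n_neg/N) <= nneg_after] )`.
#' Degenerate rates 0 or 1 use the point-mass distribution; the all-flip
#' case, whose literal tail probability is 0, is floored at the smallest
#' positive normalized double so the log-scale significance level stays
#' finite.
#'
#' @param n_pos,n_neg active / inactive counts before the transformation.
#' @param npos_after,nneg_after active / inactive counts after.
#' @return p-value in (0, 1].
#' @export
pvalue_classification <- function(n_pos, n_neg, npos_after, nneg_after) {
  n <- n_pos + n_neg
  if (n < 1L) stop("no pairs: N = 0")
  if (npos_after + nneg_after != n) {
    stop("before/after totals differ: ", n, " vs ", npos_after + nneg_after)
  }
  p <- min(binom_lower_tail(npos_after, n, n_pos / n),
           binom_lower_tail(nneg_after, n, n_neg / n))
  max(p, .Machine$double.xmin)
}

#' Significance level of a p-value
#'
#' Log-scale representation: `-log10(p)`. A p-value of 0.01 corresponds to
#' level 2, 0.001 to level 3.
#' @param p p-value(s) in (0, 1].
#' @return significance level(s) >= 0.
#' @export
significance_level <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  -log10(p)
}

#' Holm-Bonferroni rejection flags
#'
#' Step-down multiple-testing correction at family-wise error rate `alpha`;
#' flags are returned in the input order.
#' @param pvalues p-values in (0, 1].
#' @param alpha family-wise error rate in (0, 1).
#' @return logical vector: `TRUE` where the hypothesis is rejected.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(pvalues) == 0L) return(logical())
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "holm") <= alpha
}

#' Bootstrap p-value under prediction uncertainty
#'
#' Emulates the applicability-domain-aware replica analysis: each replica
#' perturbs every predicted value with independent Gaussian noise whose
#' standard deviation equals the value's estimated uncertainty (binary
#' endpoints: each predicted label flips independently with probability equal
#' to its estimated misclassification rate), the direction counts are
#' re-tallied and the p-value recomputed. Experimental values are never
#' perturbed. The replica p-values are summarised by their median, which is
#' compared to alpha downstream to drop transformations that rest on
#' unreliable predictions.
#'
#' @param deltas pair table for one transformation and endpoint, as built by
#'   [pair_deltas()] (columns `kind`, `value_a`, `value_b`, `source_a`,
#'   `source_b`, `unc_a`, `unc_b`, `sign`; `sign` may be omitted and defaults
#'   to +1).
#' @param n_replicas number of replicas (default 1000).
#' @param seed RNG seed; results are bit-for-bit reproducible.
#' @param tie_tol continuous deltas with absolute value below this are
#'   excluded from the counts.
#' @return list with `bootstrap_p` (median replica p-value) and
#'   `replica_p` (all replica p-values).
#' @export
bootstrap_significance <- function(deltas, n_replicas = 1000L, seed = 1L,
                                   tie_tol = 1e-9) {
  stopifnot(n_replicas >= 1L)
  if (is.null(deltas$sign)) deltas$sign <- 1L
  pred_a <- deltas$source_a == "predicted"
  pred_b <- deltas$source_b == "predicted"
  if (any(is.na(deltas$unc_a[pred_a])) || any(is.na(deltas$unc_b[pred_b]))) {
    stop("predicted values must carry an uncertainty")
  }
  kind <- unique(deltas$kind)
  stopifnot(length(kind) == 1L)
  n <- nrow(deltas)
  replica_p <- numeric(n_replicas)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (r in seq_len(n_replicas)) {
    if (kind == "continuous") {
      va <- deltas$value_a + ifelse(pred_a, stats::rnorm(n, 0, deltas$unc_a), 0)
      vb <- deltas$value_b + ifelse(pred_b, stats::rnorm(n, 0, deltas$unc_b), 0)
      d <- (vb - va) * deltas$sign
      n_posr <- sum(d > tie_tol)
      n_negr <- sum(d < -tie_tol)
      replica_p[r] <- if (n_posr + n_negr == 0L) 1.0 else
        binom_lower_tail(min(n_posr, n_negr), n_posr + n_negr, 0.5)
    } else {
      flip_a <- pred_a & stats::runif(n) < deltas$unc_a
      flip_b <- pred_b & stats::runif(n) < deltas$unc_b
      la <- ifelse(flip_a, flip_label(deltas$value_a), deltas$value_a)
      lb <- ifelse(flip_b, flip_label(deltas$value_b), deltas$value_b)
      before <- ifelse(deltas$sign > 0, la, lb)
      after <- ifelse(deltas$sign > 0, lb, la)
      replica_p[r] <- pvalue_classification(
        sum(before == "active"), sum(before == "inactive"),
        sum(after == "active"), sum(after == "inactive"))
    }
  }
  list(bootstrap_p = stats::median(replica_p), replica_p = replica_p)
}

flip_label <- function(x) ifelse(x == "active", "inactive", "active")

# Direction counts and p-value for one transformation's pair table.
transformation_test <- function(deltas, tie_tol = 1e-9) {
  if (deltas$kind[1L] == "continuous") {
    d <- deltas$delta * deltas$sign
    n_pos <- sum(d > tie_tol)
    n_neg <- sum(d < -tie_tol)
    n_zero <- sum(abs(d) <= tie_tol)
    p <- if (n_pos + n_neg == 0L) 1.0 else pvalue_regression(n_pos, n_neg)
    list(N = nrow(deltas), n_pos = n_pos, n_neg = n_neg, n_zero = n_zero,
         npos_after = NA_integer_, nneg_after = NA_integer_,
         mean_delta = mean(d), p_value = p,
         n_deactivated = NA_integer_, n_activated = NA_integer_)
  } else {
    before <- ifelse(deltas$sign > 0, deltas$value_a, deltas$value_b)
    after <- ifelse(deltas$sign > 0, deltas$value_b, deltas$value_a)
    n_pos <- sum(before == "active")
    n_neg <- sum(before == "inactive")
    npos_after <- sum(after == "active")
    nneg_after <- sum(after == "inactive")
    list(N = nrow(deltas), n_pos = n_pos, n_neg = n_neg, n_zero = 0L,
         npos_after = npos_after, nneg_after = nneg_after,
         mean_delta = NA_real_,
         p_value = pvalue_classification(n_pos, n_neg, npos_after,
                                         nneg_after),
         n_deactivated = sum(before == "active" & after == "inactive"),
         n_activated = sum(before == "inactive" & after == "active"))
  }
}

#' Identify significant transformations for an endpoint
#'
#' Computes per-transformation direction counts and exact binomial p-values
#' (combined evidence, and the experimental-only subset separately), applies
#' Holm-Bonferroni across all tested transformations of the endpoint, runs
#' the uncertainty bootstrap wherever predictions contribute, and assigns the
#' evidence provenance class (`experimental`, `amplified`, `predicted`,
#' `none`).
#'
#' A transformation is `significant` when it passes Holm-Bonferroni on the
#' combined evidence and, if predictions contribute, its bootstrap median
#' p-value does not exceed `alpha`. Pairs matched on nested scaffolds carry a
#' shared `pair_group`; each molecule pair is counted once per
#' transformation.
#'
#' @param transformations,pairs output of [extract_transformations()].
#' @param endpoints endpoint table.
#' @param endpoint endpoint name.
#' @param alpha significance threshold (default 0.05).
#' @param min_pairs minimum pair count for a transformation to be tested
#'   (default 5; below it the transformation is reported untested).
#' @param n_replicas bootstrap replicas (default 1000).
#' @param seed bootstrap seed.
#' @param tie_tol tie tolerance for continuous deltas.
#' @param include_out_of_domain see [pair_deltas()].
#' @return data.frame of transformation statistics, one row per
#'   transformation: counts, `mean_delta`, `p_value`, `significance_level`,
#'   `holm_significant`, `p_experimental`, `exp_significant`, `bootstrap_p`,
#'   `significant`, `provenance_class`, `n_exp_pairs`, `n_pred_pairs`,
#'   `deactivation_ratio`, `activation_ratio` (binary endpoints).
#' @export
significant_transformations <- function(transformations, pairs, endpoints,
                                        endpoint, alpha = 0.05,
                                        min_pairs = 5L, n_replicas = 1000L,
                                        seed = 1L, tie_tol = 1e-9,
                                        include_out_of_domain = FALSE) {
  pd <- pair_deltas(pairs, endpoints, endpoint,
                    include_out_of_domain = include_out_of_domain)
  rows <- vector("list", nrow(transformations))
  boot_inputs <- vector("list", nrow(transformations))
  for (i in seq_len(nrow(transformations))) {
    tid <- transformations$transformation[i]
    sub <- pd[pd$transformation == tid, , drop = FALSE]
    sub <- sub[!duplicated(sub$pair_group), , drop = FALSE]
    exp_sub <- sub[sub$provenance == "experimental", , drop = FALSE]
    row <- list(transformation = tid, endpoint = endpoint,
                left = transformations$left[i],
                right = transformations$right[i],
                n_cuts = transformations$n_cuts[i],
                N = nrow(sub),
                n_exp_pairs = nrow(exp_sub),
                n_pred_pairs = nrow(sub) - nrow(exp_sub))
    if (nrow(sub) >= min_pairs) {
      tt <- transformation_test(sub, tie_tol)
      row <- c(row, tested = TRUE, tt[setdiff(names(tt), "N")])
    } else {
      row <- c(row, tested = FALSE,
               list(n_pos = NA_integer_, n_neg = NA_integer_,
                    n_zero = NA_integer_, npos_after = NA_integer_,
                    nneg_after = NA_integer_, mean_delta = NA_real_,
                    p_value = NA_real_, n_deactivated = NA_integer_,
                    n_activated = NA_integer_))
    }
    row$p_experimental <- if (nrow(exp_sub) >= min_pairs)
      transformation_test(exp_sub, tie_tol)$p_value else NA_real_
    boot_inputs[i] <- list(
      if (isTRUE(row$tested) && row$n_pred_pairs > 0) sub else NULL)
    rows[[i]] <- row
  }
  stats <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  stats$significance_level <- ifelse(is.na(stats$p_value), NA_real_,
                                     -log10(stats$p_value))
  tested <- which(stats$tested)
  stats$holm_significant <- FALSE
  stats$holm_significant[tested] <-
    holm_bonferroni(stats$p_value[tested], alpha)
  exp_tested <- which(!is.na(stats$p_experimental))
  stats$exp_significant <- FALSE
  stats$exp_significant[exp_tested] <-
    holm_bonferroni(stats$p_experimental[exp_tested], alpha)
  stats$bootstrap_p <- NA_real_
  for (i in seq_len(nrow(stats))) {
    if (!is.null(boot_inputs[[i]]) && stats$holm_significant[i]) {
      stats$bootstrap_p[i] <- bootstrap_significance(
        boot_inputs[[i]], n_replicas = n_replicas,
        seed = seed + i, tie_tol = tie_tol)$bootstrap_p
    }
  }
  stats$bootstrap_pass <- is.na(stats$bootstrap_p) | stats$bootstrap_p <= alpha
  stats$significant <- stats$holm_significant & stats$bootstrap_pass
  stats$provenance_class <- classify_provenance(
    exp_significant = stats$exp_significant,
    combined_significant = stats$significant,
    n_exp_pairs = stats$n_exp_pairs,
    n_pred_pairs = stats$n_pred_pairs)
  # direction ratios for binary endpoints (used by the optimizer's
  # practical-effect filter)
  if (nrow(stats) && pd$kind[1L] == "binary") {
    stats$deactivation_ratio <- ifelse(stats$n_pos > 0,
                                       stats$n_deactivated / stats$n_pos,
                                       NA_real_)
    stats$activation_ratio <- ifelse(stats$n_neg > 0,
                                     stats$n_activated / stats$n_neg,
                                     NA_real_)
  } else {
    stats$deactivation_ratio <- NA_real_
    stats$activation_ratio <- NA_real_
  }
  stats$kind <- pd$kind[1L]
  rownames(stats) <- NULL
  stats
}

#' Export a transformation statistics table
#' @param stats data.frame from [significant_transformations()].
#' @param path output file.
#' @param sep separator.
#' @export
write_stats_table <- function(stats, path, sep = "\t") {
  utils::write.table(stats, path, sep = sep, row.names = FALSE, quote = FALSE)
}
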