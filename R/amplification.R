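# Prediction-driven evidence: the predictor contract, a toy additive
# predictor for testing, prediction annotation, and provenance
# classification (experimental / amplified / predicted).

#' Construct a predictor
#'
#' A predictor is a callable contract: given a data.frame of standardized
#' molecules it returns one row per input molecule, in order, with columns
#' `value`, `uncertainty` and `in_domain`. Predictors must be deterministic
#' for a fixed model state.
#'
#' @param fun function taking the molecule data.frame and returning the
#'   prediction data.frame.
#' @param endpoint endpoint name the predictor serves.
#' @param kind `"continuous"` or `"binary"`.
#' @return object of class `mmp_predictor`.
#' @export
predictor <- function(fun, endpoint, kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  stopifnot(is.function(fun))
  structure(list(fun = fun, endpoint = endpoint, kind = kind),
            class = "mmp_predictor")
}

#' Run a predictor on molecules
#' @param p an `mmp_predictor`.
#' @param mols standardized molecule data.frame.
#' @return data.frame with columns `value`, `uncertainty`, `in_domain`.
#' @export
predict_endpoint <- function(p, mols) {
  stopifnot(inherits(p, "mmp_predictor"))
  out <- p$fun(mols)
  if (nrow(out) != nrow(mols)) {
    stop("predictor returned ", nrow(out), " rows for ", nrow(mols),
         " molecules")
  }
  if (is.null(out$uncertainty)) out$uncertainty <- 0
  if (is.null(out$in_domain)) out$in_domain <- TRUE
  out
}

# Deterministic per-molecule noise: a pure function of (seed, unique_key), so
# predictions do not depend on call order or batch composition.
molecule_noise <- function(seed, keys, sd) {
  if (sd == 0) return(numeric(length(keys)))
  vapply(keys, function(k) {
    h <- sum(utf8ToInt(k) * seq_len(nchar(k))) %% 1048576L
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed((seed * 1048576L + h) %% .Machine$integer.max)
    stats::rnorm(1L, 0, sd)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Toy additive fragment-contribution predictor
#'
#' A transparent stand-in for a QSAR model, used by the synthetic fixtures:
#' the continuous prediction of a molecule is
#' `intercept + sum of contributions of its single-cut variable fragments +
#' seeded Gaussian noise`, with `uncertainty = noise_sd`. Fragments missing
#' from the contribution map contribute 0 (with a one-time warning). The
#' binary variant thresholds the noiseless score at `threshold`
#' (`active` above it) and reports the misclassification probability implied
#' by the noise level and the distance to the threshold as its uncertainty.
#'
#' @param contributions named numeric vector; names are single-attachment
#'   fragment notations such as `"[*:1]O"`.
#' @param intercept baseline value.
#' @param noise_sd prediction noise standard deviation (also reported as the
#'   uncertainty of every continuous prediction).
#' @param seed noise seed; predictions are deterministic given the seed.
#' @param endpoint endpoint name (default `"endpoint"`).
#' @param kind `"continuous"` or `"binary"`.
#' @param threshold activity threshold for the binary variant.
#' @return an `mmp_predictor`.
#' @export
toy_additive_predictor <- function(contributions, intercept = 0,
                                   noise_sd = 0, seed = 1L,
                                   endpoint = "endpoint",
                                   kind = c("continuous", "binary"),
                                   threshold = 0) {
  kind <- match.arg(kind)
  warned <- new.env(parent = emptyenv())
  score <- function(mols) {
    vapply(seq_len(nrow(mols)), function(i) {
      f <- enumerate_fragmentations(mols$smiles[i], max_cuts = 1L,
                                    hydrogen_records = FALSE)
      vars <- f$variable
      unknown <- setdiff(vars, names(contributions))
      for (u in unknown) {
        if (is.null(warned[[u]])) {
          warning("unknown fragment contributes 0: ", u, call. = FALSE)
          warned[[u]] <- TRUE
        }
      }
      intercept + sum(contributions[intersect(vars, names(contributions))])
    }, numeric(1))
  }
  fun <- function(mols) {
    s <- score(mols)
    noise <- molecule_noise(seed, mols$unique_key, noise_sd)
    if (kind == "continuous") {
      data.frame(value = s + noise, uncertainty = noise_sd, in_domain = TRUE)
    } else {
      noisy <- s + noise
      mis <- if (noise_sd > 0) stats::pnorm(-abs(s - threshold) / noise_sd)
             else rep(0, length(s))
      data.frame(value = ifelse(noisy > threshold, "active", "inactive"),
                 uncertainty = pmin(mis, 0.5), in_domain = TRUE)
    }
  }
  predictor(fun, endpoint = endpoint, kind = kind)
}

#' Wrap an external executable as a predictor
#'
#' The executable receives a SMILES list (one per line) on a file passed as
#' its last argument and must print one tab-separated line per molecule:
#' `value<TAB>uncertainty<TAB>in_domain`.
#'
#' @param command executable path.
#' @param args extra arguments placed before the input file.
#' @inheritParams predictor
#' @export
external_predictor <- function(command, endpoint,
                               kind = c("continuous", "binary"),
                               args = character()) {
  kind <- match.arg(kind)
  fun <- function(mols) {
    inp <- tempfile(fileext = ".smi")
    on.exit(unlink(inp))
    writeLines(mols$smiles, inp)
    out <- system2(command, c(args, inp), stdout = TRUE)
    parts <- strsplit(out, "\t", fixed = TRUE)
    data.frame(
      value = vapply(parts, `[[`, character(1), 1L),
      uncertainty = as.numeric(vapply(parts, `[[`, character(1), 2L)),
      in_domain = as.logical(vapply(parts, `[[`, character(1), 3L)))
  }
  predictor(fun, endpoint = endpoint, kind = kind)
}

#' Annotate molecules with predicted endpoint values
#'
#' Appends one predicted endpoint row per molecule to the endpoint table.
#' Existing experimental rows are retained alongside; downstream statistics
#' prefer experimental values and use predictions to fill gaps. Molecules on
#' which the predictor fails are excluded (no predicted row) with a warning.
#'
#' @param mols standardized molecule data.frame.
#' @param endpoints existing endpoint table (or `NULL`).
#' @param pred an `mmp_predictor`.
#' @return the augmented endpoint table.
#' @export
annotate_predictions <- function(mols, endpoints, pred) {
  res <- try(predict_endpoint(pred, mols), silent = TRUE)
  if (inherits(res, "try-error")) {
    # per-molecule fallback so one failure does not void the batch
    rows <- lapply(seq_len(nrow(mols)), function(i) {
      r <- try(predict_endpoint(pred, mols[i, , drop = FALSE]), silent = TRUE)
      if (inherits(r, "try-error")) NULL else cbind(id = mols$id[i], r)
    })
    failed <- vapply(rows, is.null, logical(1))
    if (any(failed)) {
      warning("predictor failed on ", sum(failed), " molecule(s): ",
              paste(mols$id[failed], collapse = ", "))
    }
    res <- do.call(rbind, rows[!failed])
  } else {
    res <- cbind(id = mols$id, res)
  }
  if (is.null(res) || nrow(res) == 0L) return(endpoints)
  new_rows <- data.frame(id = res$id, endpoint = pred$endpoint,
                         kind = pred$kind, value = as.character(res$value),
                         source = "predicted",
                         uncertainty = res$uncertainty,
                         in_domain = res$in_domain)
  if (is.null(endpoints)) return(new_rows)
  endpoints$value <- as.character(endpoints$value)
  rbind(endpoints, new_rows)
}

#' Classify the evidence provenance of a transformation
#'
#' `experimental`: significant on the experimental pairs alone.
#' `amplified`: not significant (or untestable) on experimental pairs alone,
#' significant on the combined evidence, with at least one experimental pair.
#' `predicted`: significant on combined evidence with no experimental pairs.
#' `none`: not significant on any evidence.
#'
#' @param exp_significant logical: significant on experimental pairs alone
#'   (after correction); untestable subsets count as `FALSE`.
#' @param combined_significant logical: significant on combined evidence.
#' @param n_exp_pairs,n_pred_pairs pair counts by provenance.
#' @return character vector of classes.
#' @export
classify_provenance <- function(exp_significant, combined_significant,
                                n_exp_pairs, n_pred_pairs) {
  ifelse(exp_significant, "experimental",
         ifelse(combined_significant & n_exp_pairs >= 1, "amplified",
                ifelse(combined_significant & n_exp_pairs == 0, "predicted",
                       "none")))
}

#' Evidence summary of transformation statistics
#'
#' Convenience view of the amplification bookkeeping.
#' @param stats data.frame from [significant_transformations()].
#' @return data.frame with transformation, endpoint, pair counts by
#'   provenance, `p_experimental`, `p_combined` and `provenance_class`.
#' @export
evidence_summary <- function(stats) {
  data.frame(transformation = stats$transformation,
             endpoint = stats$endpoint,
             n_experimental_pairs = stats$n_exp_pairs,
             n_predicted_pairs = stats$n_pred_pairs,
             p_experimental = stats$p_experimental,
             p_combined = stats$p_value,
             provenance_class = stats$provenance_class)
}
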