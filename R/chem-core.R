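# Structure normalisation, uniqueness keys, fingerprints and similarity.

#' Standardize molecules
#'
#' Parses each structure, canonicalises it and derives an InChIKey-based
#' uniqueness key. Canonicalisation is a pure function of the molecular graph:
#' any atom-order permutation of the same molecule yields the same canonical
#' SMILES and the same unique key.
#'
#' Multi-component inputs (salts, mixtures) are rejected rather than stripped
#' so that pair semantics stay unambiguous; unparseable inputs raise an error
#' that names the offending entry (and the token position for the bracket and
#' ring-closure defects that can be located without a full parse).
#'
#' @param smiles character vector of SMILES strings.
#' @param id optional character vector of identifiers (defaults to the input
#'   SMILES); must be unique.
#' @param ignore_stereo if `TRUE`, stereo descriptors are stripped before
#'   canonicalisation so that stereoisomers collapse to one record.
#' @return a `data.frame` with one row per molecule: `id`, `input`,
#'   `smiles` (canonical), `unique_key` (InChIKey), `heavy_atoms`.
#' @examples
#' \dontrun{
#' standardize_molecules(c("OCC", "Oc1ccccc1"))
#' }
#' @export
standardize_molecules <- function(smiles, id = NULL, ignore_stereo = FALSE) {
  if (is.null(id)) id <- smiles
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate molecule ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(id) != length(smiles)) stop("id and smiles lengths differ")
  out <- lapply(seq_along(smiles), function(i) {
    rec <- standardize_one(smiles[[i]], ignore_stereo = ignore_stereo)
    rec$id <- id[[i]]
    rec
  })
  df <- do.call(rbind, out)
  df[, c("id", "input", "smiles", "unique_key", "heavy_atoms")]
}

standardize_one <- function(smi, ignore_stereo = FALSE) {
  smi <- trimws(smi)
  if (!nzchar(smi)) stop("empty structure input")
  validate_smiles_tokens(smi)
  if (grepl(".", smi, fixed = TRUE)) {
    stop("multi-component structure (salt/mixture) not supported: ", smi)
  }
  if (ignore_stereo) smi <- strip_stereo(smi)
  can <- ob_convert1("SMI", "CAN", smi)
  if (is.na(can)) stop("unparseable structure: ", smi)
  if (grepl(".", can, fixed = TRUE)) {
    stop("multi-component structure (salt/mixture) not supported: ", smi)
  }
  key <- ob_convert1("SMI", "INCHIKEY", can)
  if (is.na(key)) stop("could not derive InChIKey for: ", smi)
  g <- mol_from_smiles(can)
  data.frame(id = NA_character_, input = smi, smiles = can,
             unique_key = key, heavy_atoms = heavy_atom_count(g))
}

# Cheap lexical screen so common defects are reported with a position, which
# OpenBabel's parser does not expose.
validate_smiles_tokens <- function(smi) {
  chars <- strsplit(smi, "")[[1]]
  depth <- 0L
  bracket <- FALSE
  rings <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (bracket) {
      if (ch == "]") bracket <- FALSE
    } else if (ch == "[") {
      bracket <- TRUE
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unmatched ')' at position ", i, " in: ", smi)
    } else if (ch == "%" && i + 2L <= n) {
      key <- paste0(chars[[i + 1L]], chars[[i + 2L]])
      rings[[key]] <- if (is.null(rings[[key]])) i else NULL
      i <- i + 2L
    } else if (ch %in% as.character(0:9)) {
      rings[[ch]] <- if (is.null(rings[[ch]])) i else NULL
    }
    i <- i + 1L
  }
  if (bracket) stop("unclosed '[' in: ", smi)
  if (depth != 0L) stop("unmatched '(' in: ", smi)
  open_rings <- Filter(Negate(is.null), rings)
  if (length(open_rings)) {
    stop("unclosed ring bond '", names(open_rings)[[1]], "' at position ",
         open_rings[[1]], " in: ", smi)
  }
  invisible(TRUE)
}

strip_stereo <- function(smi) {
  smi <- gsub("@{1,2}", "", smi)
  smi <- gsub("[/\\\\]", "-", smi)
  smi
}

# -- fingerprints ------------------------------------------------------------

#' Circular (ECFP) fingerprint of a molecule
#'
#' Extended-connectivity fingerprints via OpenBabel, folded to `n_bits`.
#' The bit set is a pure function of the canonical structure and therefore
#' invariant to input atom ordering.
#'
#' @param smiles a single SMILES string.
#' @param radius neighbourhood radius (ECFP diameter = 2 * radius).
#' @param n_bits folded fingerprint length; a power of two.
#' @return object of class `mmp_fingerprint`: sorted integer bit positions in
#'   `[0, n_bits)` plus the parameters.
#' @export
fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(length(smiles) == 1L, radius >= 1L)
  if (bitwAnd(n_bits, n_bits - 1L) != 0L || n_bits <= 0L) {
    stop("n_bits must be a power of two")
  }
  fingerprint_batch(smiles, radius = radius, n_bits = n_bits)[[1L]]
}

#' @importFrom ChemmineOB forEachMol fingerprint_OB
fingerprint_batch <- function(smiles, radius = 2L, n_bits = 2048L) {
  type <- paste0("ECFP", 2L * as.integer(radius))
  refs <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  if (length(refs) != length(smiles)) {
    stop("fingerprinting failed for ", length(smiles) - length(refs),
         " molecule(s); standardize first")
  }
  mat <- ChemmineOB::fingerprint_OB(refs, type)
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  lapply(seq_len(nrow(mat)), function(i) {
    raw_bits <- which(mat[i, ] != 0) - 1L
    structure(list(bits = sort(unique(raw_bits %% n_bits)),
                   n_bits = as.integer(n_bits),
                   radius = as.integer(radius)),
              class = "mmp_fingerprint")
  })
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a intersect b| / |a union b|`. Two empty bit sets are defined to have
#' similarity 1 (identical objects); fingerprints of different lengths are an
#' error.
#'
#' @param a,b `mmp_fingerprint` objects (or plain integer bit vectors, in
#'   which case `n_bits` checking is skipped).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (inherits(a, "mmp_fingerprint") && inherits(b, "mmp_fingerprint")) {
    if (a$n_bits != b$n_bits) stop("fingerprint lengths differ")
    a <- a$bits; b <- b$bits
  }
  u <- length(union(a, b))
  if (u == 0L) return(1.0)
  length(intersect(a, b)) / u
}

# -- readers / writers -------------------------------------------------------

#' Read a SMILES file
#'
#' One molecule per line; an optional second, tab- or space-separated column
#' is taken as the id.
#' @param path file path.
#' @return data.frame with columns `smiles`, `id`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  data.frame(
    smiles = vapply(parts, `[[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else p[[1L]],
                character(1))
  )
}

#' Write canonical SMILES with ids
#' @param mols data.frame from [standardize_molecules()].
#' @param path output path.
#' @export
write_smiles_file <- function(mols, path) {
  writeLines(paste(mols$smiles, mols$id, sep = "\t"), path)
}

#' Read an SDF (V2000) file as standardized molecules
#'
#' Structures are converted to SMILES with OpenBabel and then standardized;
#' the molecule title line is used as the id when present.
#' @param path SDF file path.
#' @inheritParams standardize_molecules
#' @export
read_sdf_file <- function(path, ignore_stereo = FALSE) {
  out <- ChemmineOB::convertFormatFile("SDF", "SMI", path,
                                       tempf <- tempfile(fileext = ".smi"))
  lines <- readLines(tempf)
  unlink(tempf)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, character(1), 1L)
  id <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) > 1L && nzchar(p[[2L]])) p[[2L]] else paste0("mol", i)
  }, character(1))
  standardize_molecules(smi, id = id, ignore_stereo = ignore_stereo)
}

#' Read an endpoint table
#'
#' Delimited text with header columns `id`, `endpoint`, `kind`
#' (`continuous`|`binary`), `value` (number or `active`/`inactive`),
#' `source` (`experimental`|`predicted`), `uncertainty`, `in_domain`.
#' Experimental rows are forced to uncertainty 0 and `in_domain = TRUE`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return normalised endpoint data.frame.
#' @export
read_endpoint_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  normalize_endpoints(df)
}

#' Write an endpoint table
#' @param endpoints endpoint data.frame.
#' @param path output path.
#' @param sep field separator.
#' @export
write_endpoint_table <- function(endpoints, path, sep = "\t") {
  utils::write.table(endpoints, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
}

#' Normalise an in-memory endpoint table
#'
#' Validates the required columns and value domains, fills in default
#' `uncertainty`/`in_domain` columns, and forces experimental rows to
#' uncertainty 0 and `in_domain = TRUE`. Applied automatically by
#' [read_endpoint_table()].
#' @param df endpoint data.frame (see [read_endpoint_table()] for columns).
#' @return the normalised data.frame.
#' @export
normalize_endpoints <- function(df) {
  required <- c("id", "endpoint", "kind", "value", "source")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("endpoint table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (is.null(df$uncertainty)) df$uncertainty <- 0
  if (is.null(df$in_domain)) df$in_domain <- TRUE
  df$uncertainty <- as.numeric(df$uncertainty)
  df$in_domain <- as.logical(df$in_domain)
  bad_kind <- !df$kind %in% c("continuous", "binary")
  if (any(bad_kind)) stop("unknown endpoint kind: ",
                          paste(unique(df$kind[bad_kind]), collapse = ", "))
  bad_src <- !df$source %in% c("experimental", "predicted")
  if (any(bad_src)) stop("unknown endpoint source: ",
                         paste(unique(df$source[bad_src]), collapse = ", "))
  exper <- df$source == "experimental"
  df$uncertainty[exper] <- 0
  df$in_domain[exper] <- TRUE
  if (any(df$uncertainty < 0, na.rm = TRUE)) stop("negative uncertainty")
  binv <- df$kind == "binary"
  if (any(binv) && !all(df$value[binv] %in% c("active", "inactive"))) {
    stop("binary endpoint values must be 'active' or 'inactive'")
  }
  df
}
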