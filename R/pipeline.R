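# End-to-end pipeline: index -> pairs -> significance -> graph, with a
# manifest for reproducibility.

#' Pipeline configuration
#'
#' All tunables of the analysis in one list. Defaults follow the method's
#' stated operating points: at most 40 breakable bonds per molecule, variable
#' fragments of at most 10 atoms, pair similarity at least 50%, significance
#' threshold 0.05, 1,000 bootstrap replicas.
#'
#' @param smiles_file,sdf_file molecule input (exactly one required).
#' @param endpoint_file endpoint table path.
#' @param endpoint endpoint name to analyse.
#' @param out_dir output directory.
#' @param max_cuts,max_variable_atoms,max_breakable_bonds fragmentation
#'   limits.
#' @param min_similarity pair Tanimoto threshold.
#' @param alpha significance threshold.
#' @param min_pairs minimum pairs for testing a transformation.
#' @param n_replicas bootstrap replicas.
#' @param seed RNG seed.
#' @param radius,n_bits fingerprint parameters.
#' @param include_out_of_domain keep out-of-domain predictions.
#' @param ignore_stereo drop stereo descriptors during standardization.
#' @return a config list of class `mmp_config`.
#' @export
mmp_config <- function(smiles_file = NULL, sdf_file = NULL,
                       endpoint_file = NULL, endpoint = NULL,
                       out_dir = "mmp-out",
                       max_cuts = 3L, max_variable_atoms = 10L,
                       max_breakable_bonds = 40L, min_similarity = 0.5,
                       alpha = 0.05, min_pairs = 5L, n_replicas = 1000L,
                       seed = 1L, radius = 2L, n_bits = 2048L,
                       include_out_of_domain = FALSE,
                       ignore_stereo = FALSE) {
  cfg <- list(smiles_file = smiles_file, sdf_file = sdf_file,
              endpoint_file = endpoint_file, endpoint = endpoint,
              out_dir = out_dir, max_cuts = max_cuts,
              max_variable_atoms = max_variable_atoms,
              max_breakable_bonds = max_breakable_bonds,
              min_similarity = min_similarity, alpha = alpha,
              min_pairs = min_pairs, n_replicas = n_replicas, seed = seed,
              radius = radius, n_bits = n_bits,
              include_out_of_domain = include_out_of_domain,
              ignore_stereo = ignore_stereo)
  class(cfg) <- "mmp_config"
  cfg
}

#' Run the full MMP analysis pipeline
#'
#' Standardizes the input molecules, builds the fragmentation index, finds
#' matched pairs, extracts transformations, computes significance statistics
#' for the configured endpoint, and writes all stage outputs plus a manifest
#' (input hashes, effective configuration, seed, package version) into
#' `out_dir`. Reruns with an identical configuration reproduce identical
#' statistics tables.
#'
#' @param config an [mmp_config()].
#' @param molecules optional pre-standardized molecule data.frame (overrides
#'   file input).
#' @param endpoints optional endpoint table (overrides file input).
#' @return list with `index`, `pairs`, `transformations`, `stats`, `graph`,
#'   invisibly.
#' @export
run_pipeline <- function(config, molecules = NULL, endpoints = NULL) {
  stopifnot(inherits(config, "mmp_config"))
  if (is.null(molecules)) {
    if (!is.null(config$smiles_file)) {
      if (!file.exists(config$smiles_file)) {
        stop("stage 'input': molecule file not found: ", config$smiles_file)
      }
      raw <- read_smiles_file(config$smiles_file)
      if (nrow(raw) == 0L) stop("stage 'input': no molecules in ",
                                config$smiles_file)
      molecules <- standardize_molecules(raw$smiles, id = raw$id,
                                         ignore_stereo = config$ignore_stereo)
    } else if (!is.null(config$sdf_file)) {
      molecules <- read_sdf_file(config$sdf_file,
                                 ignore_stereo = config$ignore_stereo)
    } else {
      stop("stage 'input': no molecule input configured")
    }
  }
  if (is.null(endpoints)) {
    if (is.null(config$endpoint_file)) {
      stop("stage 'input': no endpoint table configured")
    }
    endpoints <- read_endpoint_table(config$endpoint_file)
  }
  if (is.null(config$endpoint)) {
    eps <- unique(endpoints$endpoint)
    if (length(eps) != 1L) {
      stop("stage 'input': endpoint not configured and table has ",
           length(eps), " endpoints")
    }
    config$endpoint <- eps
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  index <- build_index(molecules, max_cuts = config$max_cuts,
                       max_variable_atoms = config$max_variable_atoms,
                       max_breakable_bonds = config$max_breakable_bonds)
  write_smiles_file(index$molecules, file.path(config$out_dir,
                                               "molecules.smi"))
  utils::write.table(index$fragmentations,
                     file.path(config$out_dir, "fragmentations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  pairs <- find_matched_pairs(index, min_similarity = config$min_similarity,
                              radius = config$radius, n_bits = config$n_bits)
  if (nrow(pairs) == 0L) {
    stop("stage 'pairs': no matched pairs found")
  }
  tx <- extract_transformations(pairs)
  write_pairs_table(tx$pairs, file.path(config$out_dir, "pairs.tsv"))
  write_transformations(tx$transformations,
                        file.path(config$out_dir, "transformations.smirks"))
  stats <- significant_transformations(
    tx$transformations, tx$pairs, endpoints, config$endpoint,
    alpha = config$alpha, min_pairs = config$min_pairs,
    n_replicas = config$n_replicas, seed = config$seed,
    include_out_of_domain = config$include_out_of_domain)
  write_stats_table(stats, file.path(config$out_dir, "stats.tsv"))
  graph <- build_graph(stats)
  if (igraph::ecount(graph) > 0L) {
    export_graph(graph, file.path(config$out_dir, "graph.graphml"),
                 "graphml")
    export_graph(graph, file.path(config$out_dir, "graph.dot"), "dot")
  }
  manifest <- list(
    package = "mmpamp",
    version = as.character(utils::packageVersion("mmpamp")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    inputs = manifest_hashes(c(config$smiles_file, config$sdf_file,
                               config$endpoint_file)),
    n_molecules = nrow(index$molecules),
    n_pairs = nrow(pairs),
    n_transformations = nrow(tx$transformations),
    n_significant = sum(stats$significant, na.rm = TRUE))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(molecules = molecules, index = index, pairs = tx$pairs,
                 transformations = tx$transformations, stats = stats,
                 graph = graph, config = config))
}

manifest_hashes <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (!length(paths)) return(list())
  h <- tools::md5sum(unlist(paths))
  as.list(h)
}
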