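# Transformation graph and delta-pair chart.

#' Build the directed transformation graph
#'
#' Nodes are fragments; each significant transformation contributes one
#' directed edge pointing from the lower-property fragment to the
#' higher-property fragment (continuous endpoints: the direction of
#' increasing value; binary endpoints: toward the higher active fraction).
#' Edge attributes carry the effect size, significance level, pair count and
#' provenance class.
#'
#' @param stats data.frame from [significant_transformations()], one
#'   endpoint only; only `significant` rows are used.
#' @return an [igraph::igraph] directed graph.
#' @export
build_graph <- function(stats) {
  if (length(unique(stats$endpoint)) > 1L) {
    stop("stats mix endpoints: ",
         paste(unique(stats$endpoint), collapse = ", "))
  }
  sig <- stats[isTRUE_vec(stats$significant), , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(igraph::make_empty_graph(directed = TRUE))
  }
  if (sig$kind[1L] == "continuous") {
    fwd <- sig$mean_delta >= 0
    effect <- abs(sig$mean_delta)
  } else {
    fwd <- sig$npos_after >= sig$n_pos
    effect <- abs(sig$npos_after - sig$n_pos) / sig$N
  }
  edges <- data.frame(
    from = ifelse(fwd, sig$left, sig$right),
    to = ifelse(fwd, sig$right, sig$left),
    transformation = sig$transformation,
    effect = effect,
    significance_level = sig$significance_level,
    n_pairs = sig$N,
    provenance_class = sig$provenance_class)
  igraph::graph_from_data_frame(edges, directed = TRUE)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Export a transformation graph
#'
#' @param graph graph from [build_graph()].
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @export
export_graph <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(graph, path, format = format)
  invisible(path)
}

quadrant_of <- function(e, p) {
  # sign quadrants: (+,+)=1, (-,+)=2, (-,-)=3, (+,-)=4; zeros take the
  # lower adjacent quadrant index
  q <- function(se, sp) {
    if (se > 0 && sp > 0) 1L else if (se < 0 && sp > 0) 2L
    else if (se < 0 && sp < 0) 3L else 4L
  }
  cands <- c()
  for (se in (if (e == 0) c(1, -1) else sign(e))) {
    for (sp in (if (p == 0) c(1, -1) else sign(p))) {
      cands <- c(cands, q(se, sp))
    }
  }
  min(cands)
}

#' Delta-pair table: experimental vs predicted pair effects
#'
#' For every matched pair carrying both an experimental and a predicted
#' continuous delta, reports the two deltas, the sign quadrant of the
#' (experimental, predicted) plane, and whether the pair is a mispredicted
#' activity cliff (discordant signs, quadrant 2 or 4, with either effect at
#' least `cliff_threshold`). Zero deltas sit on an axis; they are assigned
#' the adjacent quadrant with the lower index and flagged `on_axis`. Rows are
#' ordered by decreasing `|experimental_delta|`.
#'
#' @param pairs pair data.frame (from [find_matched_pairs()] or
#'   [extract_transformations()]; a `sign` column, when present, orients the
#'   deltas along the canonical transformation direction).
#' @param endpoints endpoint table holding experimental and predicted rows
#'   for the endpoint.
#' @param endpoint endpoint name (continuous).
#' @param cliff_threshold minimal absolute effect for a cliff (default 1.0
#'   log unit).
#' @return data.frame with one row per usable pair: `pair_group`,
#'   `experimental_delta`, `predicted_delta`, `quadrant`, `on_axis`,
#'   `is_mispredicted_cliff`; attribute `n_skipped` counts pairs missing
#'   either delta.
#' @export
delta_pair_table <- function(pairs, endpoints, endpoint,
                             cliff_threshold = 1.0) {
  sgn <- if (is.null(pairs$sign)) rep(1L, nrow(pairs)) else pairs$sign
  exp_rows <- endpoints[endpoints$source == "experimental", , drop = FALSE]
  prd_rows <- endpoints[endpoints$source == "predicted", , drop = FALSE]
  de <- delta_from(pairs, exp_rows, endpoint) * sgn
  dp <- delta_from(pairs, prd_rows, endpoint) * sgn
  usable <- !is.na(de) & !is.na(dp)
  out <- data.frame(
    pair_group = pairs$pair_group[usable],
    transformation = if (is.null(pairs$transformation)) NA_character_
                     else pairs$transformation[usable],
    experimental_delta = de[usable],
    predicted_delta = dp[usable])
  out$quadrant <- mapply(quadrant_of, out$experimental_delta,
                         out$predicted_delta)
  out$on_axis <- out$experimental_delta == 0 | out$predicted_delta == 0
  out$is_mispredicted_cliff <- out$quadrant %in% c(2L, 4L) &
    pmax(abs(out$experimental_delta), abs(out$predicted_delta)) >=
      cliff_threshold
  out <- out[order(-abs(out$experimental_delta)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!usable)
  out
}

delta_from <- function(pairs, ep, endpoint) {
  ep <- ep[ep$endpoint == endpoint & ep$kind == "continuous", , drop = FALSE]
  va <- as.numeric(ep$value[match(pairs$mol_a, ep$id)])
  vb <- as.numeric(ep$value[match(pairs$mol_b, ep$id)])
  vb - va
}

#' Scatter plot of a delta-pair table
#'
#' Optional static chart (requires ggplot2): experimental vs predicted pair
#' deltas with mispredicted cliffs highlighted.
#' @param rows data.frame from [delta_pair_table()].
#' @return a ggplot object.
#' @export
plot_delta_pairs <- function(rows) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$experimental_delta,
                                     y = .data$predicted_delta,
                                     colour = .data$is_mispredicted_cliff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#2166ac",
                                            `TRUE` = "#b2182b"),
                                 name = "mispredicted cliff") +
    ggplot2::labs(x = "experimental pair delta",
                  y = "predicted pair delta")
}
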