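#' Build the weighted variability-correlation network
#'
#' Constructs a complete weighted graph over a subset of variables with edge
#' weight equal to the pairwise correlation coefficient (sign preserved; no
#' thresholding -- a display cutoff is a plotting concern only).
#'
#' @param corr a [correlation_matrix()] result, or a square correlation
#'   matrix with dimnames.
#' @param subset node subset (default: all variables).
#' @return An object of class `vn_network`: list with `nodes`, `edges`
#'   (data.frame source, target, weight) and the igraph object `graph`.
#' @export
build_graph <- function(corr, subset = NULL) {
  r <- if (inherits(corr, "vn_corr")) corr$r else as.matrix(corr)
  if (is.null(subset)) subset <- rownames(r)
  if (length(subset) < 2)
    vn_stop("a network needs at least 2 nodes", "varnet_input_error")
  if (!all(subset %in% rownames(r)))
    vn_stop("subset must be contained in the correlation variables",
            "varnet_input_error")
  r <- r[subset, subset]
  pairs <- t(utils::combn(subset, 2))
  edges <- data.frame(source = pairs[, 1], target = pairs[, 2],
                      weight = r[pairs], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = subset))
  structure(list(nodes = subset, edges = edges, graph = g),
            class = "vn_network")
}

#' Fruchterman-Reingold layout of a variability network
#'
#' Force-directed 2-D layout where attraction scales with the absolute edge
#' weight, so strongly correlated variabilities sit close together. The
#' layout is deterministic given `seed`.
#'
#' @param network a [build_graph()] result.
#' @param seed RNG seed (recorded in the result).
#' @param iterations number of FR iterations.
#' @return matrix of coordinates (nodes x 2) with attribute `"seed"`.
#' @export
fr_layout <- function(network, seed = 42, iterations = 500) {
  stopifnot(inherits(network, "vn_network"))
  set.seed(seed)
  ## zero-weight edges exert no attraction: drop them for the layout
  g <- network$graph
  w <- abs(igraph::E(g)$weight)
  g <- igraph::delete_edges(g, which(w == 0))
  xy <- igraph::layout_with_fr(g, weights = abs(igraph::E(g)$weight),
                               niter = iterations)
  dimnames(xy) <- list(network$nodes, c("x", "y"))
  attr(xy, "seed") <- seed
  xy
}

#' Weighted centralities of a variability network
#'
#' Node strength is the sum of absolute incident edge weights. Path-based
#' centralities (closeness, betweenness) use edge length `1 / |weight|`, the
#' usual weighted-network convention, so strong correlations are short edges.
#' Zero-weight edges are dropped from the path metrics; a node left with no
#' edges gets strength 0 and `NA` closeness.
#'
#' @param network a [build_graph()] result.
#' @return data.frame with columns node, strength, closeness, betweenness.
#' @export
centralities <- function(network) {
  stopifnot(inherits(network, "vn_network"))
  g <- network$graph
  w <- abs(igraph::E(g)$weight)
  strength <- igraph::strength(g, weights = w)
  gp <- igraph::delete_edges(g, which(w == 0))
  wl <- 1 / abs(igraph::E(gp)$weight)
  clo <- suppressWarnings(igraph::closeness(gp, weights = wl))
  btw <- igraph::betweenness(gp, weights = wl)
  iso <- igraph::degree(gp) == 0
  clo[iso] <- NA_real_
  data.frame(node = network$nodes,
             strength = unname(strength[network$nodes]),
             closeness = unname(clo[network$nodes]),
             betweenness = unname(btw[network$nodes]),
             stringsAsFactors = FALSE)
}

#' Export a network to GraphML and edge-list CSV
#'
#' @param network a [build_graph()] result.
#' @param graphml,edges_csv output paths (either may be `NULL` to skip).
#' @return invisible `NULL`.
#' @export
export_network <- function(network, graphml = NULL, edges_csv = NULL) {
  stopifnot(inherits(network, "vn_network"))
  if (!is.null(graphml))
    igraph::write_graph(network$graph, graphml, format = "graphml")
  if (!is.null(edges_csv))
    utils::write.csv(network$edges, edges_csv, row.names = FALSE)
  invisible(NULL)
}

#' @export
print.vn_network <- function(x, ...) {
  cat(sprintf("Variability network: %d nodes, %d edges, |weight| range %.3f-%.3f\n",
              length(x$nodes), nrow(x$edges),
              min(abs(x$edges$weight)), max(abs(x$edges$weight))))
  invisible(x)
}

#' Plot a variability network
#'
#' @param x a [build_graph()] result.
#' @param layout coordinates from [fr_layout()] (computed if missing).
#' @param min_abs_weight display cutoff for edges (rendering only; the
#'   analysis never thresholds).
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.vn_network <- function(x, layout = NULL, min_abs_weight = 0, ...) {
  if (is.null(layout)) layout <- fr_layout(x)
  g <- x$graph
  w <- igraph::E(g)$weight
  g <- igraph::delete_edges(g, which(abs(w) < min_abs_weight))
  w <- igraph::E(g)$weight
  igraph::plot.igraph(g, layout = layout,
                      edge.width = 3 * abs(w),
                      edge.color = ifelse(w >= 0, "darkgreen", "firebrick"),
                      vertex.size = 14, vertex.color = "grey90", ...)
  invisible(x)
}
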