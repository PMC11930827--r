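#' Edge length for shortest-path centralities
#'
#' Strongly associated diseases are "close": an edge of weight `w` has
#' length `1/|w|`, so larger absolute weights give shorter distances. A zero
#' weight is no edge at all, never a zero-length edge.
#'
#' @param w nonzero edge weight(s).
#' @return numeric distance(s).
#' @export
edge_distance <- function(w) {
  if (any(w == 0)) stop("zero weight is no edge, not a zero-length edge")
  1 / abs(w)
}

as_distance_graph <- function(net) {
  w <- net$w
  g <- igraph::graph_from_adjacency_matrix(abs(w), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$distance <- 1 / igraph::E(g)$weight
  g
}

#' Node strength
#'
#' Sum of the absolute weights of a node's incident edges. Absolute values
#' keep strength nonnegative in the presence of negative (decentralized
#' co-occurrence) associations.
#'
#' @param net an `ising_network` (or list with symmetric `w`).
#' @param i node index/label, or `NULL` for all nodes.
#' @return named numeric vector (or scalar).
#' @export
strength <- function(net, i = NULL) {
  s <- rowSums(abs(net$w))
  if (is.null(i)) s else s[i]
}

#' Closeness centrality over association distances
#'
#' `1 / sum(d(i, j))` over all nodes `j` reachable from `i`, with shortest
#' paths taken over [edge_distance()] lengths. Unnormalized, as in the
#' study's tables (values around 0.004-0.008 at 38 nodes). An isolated node
#' has no defined closeness and is returned as `NA` (printed `-`).
#'
#' @inheritParams strength
#' @return named numeric vector with `NA` for isolated nodes.
#' @export
closeness <- function(net, i = NULL) {
  g <- as_distance_graph(net)
  d <- igraph::distances(g, weights = igraph::E(g)$distance)
  diag(d) <- Inf   # exclude self
  tot <- apply(d, 1, function(row) sum(row[is.finite(row)]))
  cl <- ifelse(tot > 0, 1 / tot, NA_real_)
  names(cl) <- colnames(net$w)
  if (is.null(i)) cl else cl[i]
}

#' Betweenness centrality over association distances
#'
#' Number of shortest paths between other node pairs passing through the
#' node (endpoints excluded; tied geodesics split fractionally), with path
#' lengths from [edge_distance()].
#'
#' @inheritParams strength
#' @return named numeric vector.
#' @export
betweenness <- function(net, i = NULL) {
  g <- as_distance_graph(net)
  b <- igraph::betweenness(g, weights = igraph::E(g)$distance,
                           directed = FALSE)
  b <- setNames(as.numeric(b), colnames(net$w))
  if (is.null(i)) b else b[i]
}

#' Centrality table for all diseases
#'
#' Strength, closeness and betweenness per node, in the layout of the
#' study's centrality table: betweenness is reported both raw and rounded
#' to integer (the published table prints integers), and missing closeness
#' of isolated nodes prints as `-` in the TSV output.
#'
#' @param net an `ising_network`.
#' @return a `centrality_table` data frame with columns `node`, `strength`,
#'   `closeness`, `betweenness`, `betweenness_int`.
#' @export
centrality_table <- function(net) {
  out <- data.frame(
    node = colnames(net$w),
    strength = unname(strength(net)),
    closeness = unname(closeness(net)),
    betweenness = unname(betweenness(net)),
    stringsAsFactors = FALSE)
  out$betweenness_int <- as.integer(round_half_up(out$betweenness))
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Write a centrality table as TSV
#'
#' @param tab a `centrality_table`.
#' @param path output file.
#' @param digits significant digits for the numeric columns.
#' @return `path`, invisibly. Missing closeness is written as `-`.
#' @export
write_centrality_table <- function(tab, path, digits = 4) {
  out <- tab
  out$strength <- signif(out$strength, digits)
  out$closeness <- ifelse(is.na(out$closeness), "-",
                          format(signif(out$closeness, digits)))
  out$betweenness <- signif(out$betweenness, digits)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
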