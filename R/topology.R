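to_igraph_input <- function(g) {
  if (inherits(g, c("lclmn", "triple_network"))) g <- as_igraph(g)
  if (!igraph::is_igraph(g)) {
    stop("expected an 'lclmn', 'triple_network' or igraph object",
         call. = FALSE)
  }
  g
}

#' Degree, betweenness and closeness centrality of a ceRNA network
#'
#' Treats the network as undirected and unweighted. Degree is the
#' incident-edge count; betweenness sums, over unordered node pairs
#' `s != t != v`, the fraction of shortest s-t paths passing through `v`;
#' closeness is the unnormalized reciprocal of the summed shortest-path
#' distances from a node to every node it can reach. No `(n-1)(n-2)/2` or
#' `n-1` rescaling is applied, so values are comparable with raw
#' shortest-path counts. On disconnected graphs betweenness is accumulated
#' within components and closeness sums only over the reachable set.
#'
#' @param g An `lclmn`, `triple_network` or undirected igraph object with at
#'   least one edge.
#'
#' @return Data frame with columns `node`, `class` (vertex attribute if
#'   present, else `NA`), `degree`, `betweenness`, `closeness`.
#' @export
compute_centralities <- function(g) {
  ig <- to_igraph_input(g)
  if (igraph::ecount(ig) == 0L) {
    stop("the graph has no edges", call. = FALSE)
  }
  deg <- igraph::degree(ig)
  btw <- igraph::betweenness(ig, directed = FALSE, weights = NA,
                             normalized = FALSE)
  D <- igraph::distances(ig, weights = NA)
  clo <- apply(D, 1L, function(row) {
    s <- sum(row[is.finite(row)])
    if (s > 0) 1 / s else 0
  })
  cls <- if ("class" %in% igraph::vertex_attr_names(ig)) {
    igraph::vertex_attr(ig, "class")
  } else {
    NA_character_
  }
  data.frame(
    node = igraph::V(ig)$name,
    class = cls,
    degree = unname(deg),
    betweenness = unname(btw),
    closeness = unname(clo),
    stringsAsFactors = FALSE
  )
}

#' Intersect the top-k nodes of the three centrality dimensions
#'
#' Ranks nodes descending within each dimension (degree, betweenness,
#' closeness), takes the top `k` of each — nodes tied with the k-th value are
#' included rather than arbitrarily cut — intersects the three sets, and
#' finally restricts to one node class to nominate hub candidates.
#'
#' @param table A [compute_centralities()] result.
#' @param k Number of top nodes per dimension (default 10). When `k` exceeds
#'   the node count, all nodes are used with a warning.
#' @param restrict_class Keep only nodes of this class in the overlap
#'   (default `"lncRNA"`); `NULL` keeps every class.
#'
#' @return Sorted character vector of node ids.
#' @export
top_k_overlap <- function(table, k = 10L, restrict_class = "lncRNA") {
  stopifnot(is.data.frame(table), nrow(table) > 0L, k >= 1L)
  if (k > nrow(table)) {
    warning("k exceeds the node count; using all nodes")
    k <- nrow(table)
  }
  top_set <- function(values) {
    threshold <- sort(values, decreasing = TRUE)[k]
    table$node[values >= threshold]
  }
  overlap <- Reduce(intersect, list(top_set(table$degree),
                                    top_set(table$betweenness),
                                    top_set(table$closeness)))
  if (!is.null(restrict_class)) {
    overlap <- overlap[table$class[match(overlap, table$node)] %in%
                         restrict_class]
  }
  sort(overlap)
}
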