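#' Filter PPI edges by confidence score
#'
#' Keeps edges with score at or above `minScore` (the 0-1000 integer scale;
#' 0.8 on the STRING probability scale is 800). Isolated nodes are retained.
#'
#' @param g igraph with a `score` edge attribute in `[0, 1000]`.
#' @param minScore inclusive score threshold (default 800).
#' @return The filtered igraph.
#' @export
filterEdges <- function(g, minScore = 800) {
  sc <- igraph::E(g)$score
  stopifnot(!is.null(sc), all(sc >= 0 & sc <= 1000))
  igraph::delete_edges(g, igraph::E(g)[sc < minScore])
}

#' Enumerate maximal cliques
#'
#' All maximal cliques of a simple undirected graph (Bron-Kerbosch with
#' pivoting, via igraph). Each clique is returned as a sorted character
#' vector of vertex names; an isolated vertex is its own maximal clique.
#'
#' @param g simple undirected igraph with named vertices.
#' @return List of sorted character vectors.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' maximalCliques(g)
#' @export
maximalCliques <- function(g) {
  stopifnot(igraph::is_simple(g), !igraph::is_directed(g))
  cl <- igraph::max_cliques(g)
  lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
}

#' Maximal clique centrality ranking
#'
#' `MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!`. An
#' isolated node's only maximal clique is itself, contributing 0! = 1. Nodes
#' are ranked by descending MCC with deterministic tie-break by node id; the
#' hub flag marks the top `hubFraction` (ceiling) of nodes.
#'
#' @param g simple undirected igraph (typically the output of
#'   [filterEdges()]).
#' @param hubFraction fraction of nodes flagged as hubs (study: 0.30).
#' @return data.frame: node, mcc, rank, hub; ordered by rank.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, a - c)
#' mccScores(g)
#' @export
mccScores <- function(g, hubFraction = 0.30) {
  nodes <- igraph::V(g)$name
  mcc <- setNames(numeric(length(nodes)), nodes)
  for (cl in maximalCliques(g)) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  }
  ord <- order(-mcc, nodes)
  out <- data.frame(node = nodes[ord], mcc = unname(mcc[ord]))
  out$rank <- seq_len(nrow(out))
  out$hub <- out$rank <= ceiling(hubFraction * nrow(out))
  out
}

#' Hub differentially expressed genes
#'
#' Intersects the hub set of an MCC ranking with a DEG list, ordered by
#' descending MCC. `scope = "degs"` instead restricts the ranking to the DEG
#' nodes first and takes the top fraction of those (both readings of the
#' "top 30%" rule are provided).
#'
#' @param ranking data.frame from [mccScores()].
#' @param degs character vector of DEG ids.
#' @param scope `"all"` (hubs among all network nodes, then intersect) or
#'   `"degs"` (top fraction of DEG nodes by MCC).
#' @param hubFraction used for `scope = "degs"` (default 0.30).
#' @return data.frame of hub DEGs with their mcc, ordered by mcc descending.
#' @export
hubDegs <- function(ranking, degs, scope = c("all", "degs"),
                    hubFraction = 0.30) {
  scope <- match.arg(scope)
  if (scope == "all") {
    out <- ranking[ranking$hub & ranking$node %in% degs, c("node", "mcc")]
  } else {
    sub <- ranking[ranking$node %in% degs, c("node", "mcc")]
    sub <- sub[order(-sub$mcc, sub$node), ]
    out <- head(sub, ceiling(hubFraction * nrow(sub)))
  }
  rownames(out) <- NULL
  out
}
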