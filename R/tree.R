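#' Strongest-weight spanning tree by descending-order Kruskal
#'
#' Sorts edges into descending weight order and accepts each edge unless it
#' closes a loop, until all nodes are connected by n - 1 edges. This is the
#' maximum-total-weight spanning tree of the network; "minimum spanning tree"
#' in the MST brain-network literature refers to this strongest-connection
#' tree. Ties are broken deterministically by (smaller first node, then
#' smaller second node).
#'
#' @param W Symmetric numeric weight matrix (no NAs off the diagonal).
#' @param node_labels Optional character labels for the nodes; defaults to
#'   rownames of `W` or `"n<q>"`.
#' @param abs_weights If TRUE, sort by absolute weight instead of the raw
#'   (signed) weight. Default FALSE: raw correlation weights are sorted.
#' @return Object of class `homst_tree`: fields `n`, `edges` (data frame
#'   `from, to, weight`), `node_labels`.
#' @export
kruskal_strongest_tree <- function(W, node_labels = NULL, abs_weights = FALSE) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be a square matrix")
  n <- nrow(W)
  if (n < 2) stop("need at least 2 nodes")
  if (is.null(node_labels))
    node_labels <- if (!is.null(rownames(W))) rownames(W) else paste0("n", seq_len(n))
  ut <- upper.tri(W)
  w <- W[ut]
  if (anyNA(w) || any(!is.finite(w))) stop("edge weights must be finite")
  ei <- row(W)[ut]
  ej <- col(W)[ut]
  key <- if (abs_weights) abs(w) else w
  ord <- order(-key, ei, ej)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  from <- integer(n - 1L); to <- integer(n - 1L); wt <- numeric(n - 1L)
  taken <- 0L
  for (e in ord) {
    ra <- find(ei[e]); rb <- find(ej[e])
    if (ra != rb) {
      parent[ra] <- rb
      taken <- taken + 1L
      from[taken] <- ei[e]; to[taken] <- ej[e]; wt[taken] <- w[e]
      if (taken == n - 1L) break
    }
  }
  if (taken < n - 1L) stop("graph is disconnected; no spanning tree exists")
  structure(list(n = n,
                 edges = data.frame(from = from, to = to, weight = wt),
                 node_labels = node_labels),
            class = "homst_tree")
}

tree_igraph <- function(tree) {
  igraph::graph_from_edgelist(cbind(tree$edges$from, tree$edges$to),
                              directed = FALSE)
}

#' Local node metrics of a spanning tree
#'
#' Degree (incident edge count), eccentricity (longest shortest path in hops
#' to any other node) and betweenness centrality
#' `BC_i = 1/((n-1)(n-2)) * sum_{h != j, both != i} rho_hj(i) / rho_hj`
#' over ordered node pairs, so a star center attains exactly 1. On a tree
#' every shortest path is unique (`rho_hj = 1`).
#'
#' @param tree A `homst_tree`, needing at least 3 nodes (the betweenness
#'   normalizer is undefined below that).
#' @return Data frame with columns `node, label, degree, eccentricity,
#'   betweenness`.
#' @export
tree_metrics <- function(tree) {
  n <- tree$n
  if (n < 3) stop("betweenness centrality is undefined for trees with n < 3")
  g <- tree_igraph(tree)
  deg <- as.integer(igraph::degree(g))
  D <- igraph::distances(g, weights = NA)
  ecc <- apply(D, 1, max)
  bc <- 2 * igraph::betweenness(g, weights = NA, normalized = FALSE) /
    ((n - 1) * (n - 2))
  data.frame(node = seq_len(n), label = tree$node_labels,
             degree = deg, eccentricity = as.integer(ecc),
             betweenness = as.numeric(bc))
}

#' Write a tree as an edge-list TSV (and optionally GraphML)
#'
#' @param tree A `homst_tree`.
#' @param path Output TSV path (columns `node_q, node_r, weight`).
#' @param graphml Optional GraphML output path.
#' @export
write_tree <- function(tree, path, graphml = NULL) {
  e <- tree$edges
  out <- data.frame(node_q = tree$node_labels[e$from],
                    node_r = tree$node_labels[e$to],
                    weight = e$weight)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(graphml)) {
    g <- tree_igraph(tree)
    igraph::V(g)$name <- tree$node_labels
    igraph::E(g)$weight <- e$weight
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
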