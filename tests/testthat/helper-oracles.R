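# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: spanning trees by exhaustive enumeration,
# betweenness by path enumeration, frequent subgraphs by brute-force subset
# enumeration with an igraph (BLISS) canonical form.

random_weight_graph <- function(n) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2, -1, 1)
  W + t(W)
}

# maximum spanning-tree weight by enumerating all (n-1)-edge subsets,
# with a tiny union-find spanning check
oracle_max_tree_weight <- function(W) {
  n <- nrow(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  spans <- function(e) {
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (r in seq_len(nrow(e))) {
      ra <- find(e[r, 1]); rb <- find(e[r, 2])
      if (ra == rb) return(FALSE)  # cycle in an (n-1)-edge subset
      parent[ra] <- rb
    }
    TRUE
  }
  best <- -Inf
  for (sub in utils::combn(nrow(idx), n - 1, simplify = FALSE)) {
    e <- idx[sub, , drop = FALSE]
    if (spans(e)) best <- max(best, sum(W[e]))
  }
  best
}

random_tree_edges <- function(n) {
  # random labeled tree: attach each node to a uniformly chosen predecessor
  if (n < 2) return(matrix(integer(0), 0, 2))
  cbind(sapply(2:n, function(v) sample(v - 1, 1)), 2:n)
}

# betweenness via explicit enumeration of the unique tree path of every
# ordered pair (BFS parent trace), normalized by (n-1)(n-2)
oracle_tree_betweenness <- function(edges, n) {
  adj <- lapply(seq_len(n), function(v)
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  path_between <- function(a, b) {
    parent <- rep(NA_integer_, n)
    seen <- logical(n); seen[a] <- TRUE
    queue <- a
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
      }
    }
    path <- b
    while (path[1] != a) path <- c(parent[path[1]], path)
    path
  }
  counts <- numeric(n)
  for (h in seq_len(n)) for (j in seq_len(n)) if (h != j) {
    interior <- setdiff(path_between(h, j), c(h, j))
    counts[interior] <- counts[interior] + 1
  }
  counts / ((n - 1) * (n - 2))
}

to_igraph_labeled <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

# canonical key via igraph's BLISS canonical permutation with label colors
oracle_canonical_key <- function(g) {
  if (g$n == 0) return("empty")
  lab_levels <- sort(unique(g$labels))
  ig <- to_igraph_labeled(g)
  perm <- igraph::canonical_permutation(
    ig, colors = match(g$labels, lab_levels))$labeling
  new_edges <- cbind(perm[g$edges[, 1]], perm[g$edges[, 2]])
  new_labels <- character(g$n)
  new_labels[perm] <- g$labels
  es <- if (nrow(new_edges)) {
    e <- cbind(pmin(new_edges[, 1], new_edges[, 2]),
               pmax(new_edges[, 1], new_edges[, 2]))
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    paste(e[, 1], e[, 2], sep = "-", collapse = ";")
  } else ""
  paste(paste(new_labels, collapse = ","), es, sep = "|")
}

subgraph_from_edge_subset <- function(g, edge_rows) {
  e <- g$edges[edge_rows, , drop = FALSE]
  nodes <- sort(unique(c(e)))
  labeled_graph(cbind(match(e[, 1], nodes), match(e[, 2], nodes)),
                g$labels[nodes])
}

# all frequent connected patterns by exhaustive edge-subset enumeration,
# returned as canonical-key -> frequency
oracle_frequent_patterns <- function(G, min_fq) {
  keysets <- lapply(G, function(g) {
    m <- nrow(g$edges)
    keys <- character(0)
    if (m > 0) for (sz in seq_len(m)) {
      for (sub in utils::combn(m, sz, simplify = FALSE)) {
        sg <- subgraph_from_edge_subset(g, sub)
        if (homst:::graph_is_connected(sg))
          keys <- c(keys, oracle_canonical_key(sg))
      }
    }
    unique(keys)
  })
  tab <- table(unlist(keysets))
  fq <- as.numeric(tab) / length(G)
  keep <- fq >= min_fq - 1e-9
  stats::setNames(fq[keep], names(tab)[keep])
}

random_labeled_graph <- function(n_nodes, n_edges, alphabet) {
  all_pairs <- utils::combn(n_nodes, 2)
  pick <- sample(ncol(all_pairs), min(n_edges, ncol(all_pairs)))
  labeled_graph(t(all_pairs[, pick, drop = FALSE]),
                sample(alphabet, n_nodes, replace = TRUE))
}

small_cohort_features <- function(seed, n_per_group = 5, effect_size = 0,
                                  R = 6, M = 60) {
  cc <- cohort_config(n_per_group = n_per_group, R = R, M = M,
                      effect_pairs = list(c(1L, 2L), c(3L, 4L)),
                      effect_size = effect_size, noise_sd = 0.2, seed = seed)
  extract_features(generate_cohort(cc), N = 15L, S = 3L)
}

fast_protocol <- function(seed = 1L) {
  eval_protocol(a_grid = c(0, 0.5, 1), cost_grid = 1, inner_folds = 3L,
                fq_pos = 0.4, fq_neg = 0.4, k_patterns = 5L, wl_h = 2L,
                seed = seed)
}
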