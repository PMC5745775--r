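#' Undirected labeled graph
#'
#' Node-labeled undirected graph used for spanning-tree mining and graph
#' kernels. Self-loops are rejected; duplicate edges are collapsed. Node
#' labels default to pair-node identities, under which any two subjects'
#' graphs share a common node universe.
#'
#' @param edges Integer matrix (m x 2) of node indices, or NULL/0-row for an
#'   edgeless graph.
#' @param labels Character vector of node labels (length = node count).
#' @return Object of class `homst_graph`: fields `n`, `labels`, `edges`
#'   (m x 2 with first column smaller).
#' @export
labeled_graph <- function(edges, labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (is.null(edges) || length(edges) == 0) {
    edges <- matrix(integer(0), 0, 2)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2)
    if (any(edges < 1 | edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(n = n, labels = labels, edges = edges), class = "homst_graph")
}

#' Build a labeled graph from label pairs
#'
#' Nodes are the distinct labels occurring in `pairs` (sorted); each row of
#' `pairs` becomes one edge.
#'
#' @param pairs Character matrix (m x 2) of endpoint labels.
#' @return A [labeled_graph()].
#' @export
graph_from_label_pairs <- function(pairs) {
  pairs <- matrix(as.character(pairs), ncol = 2)
  labels <- sort(unique(c(pairs)))
  labeled_graph(cbind(match(pairs[, 1], labels), match(pairs[, 2], labels)),
                labels)
}

adjacency_list <- function(g) {
  adj <- vector("list", g$n)
  if (nrow(g$edges)) {
    for (e in seq_len(nrow(g$edges))) {
      a <- g$edges[e, 1]; b <- g$edges[e, 2]
      adj[[a]] <- rbind(adj[[a]], c(b, e))
      adj[[b]] <- rbind(adj[[b]], c(a, e))
    }
  }
  adj
}

graph_is_connected <- function(g) {
  if (g$n <= 1) return(TRUE)
  adj <- adjacency_list(g)
  seen <- logical(g$n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    if (!is.null(nb)) {
      new <- nb[!seen[nb[, 1]], 1]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  all(seen)
}

has_unique_labels <- function(g) !anyDuplicated(g$labels)

edge_label_keys <- function(g) {
  if (!nrow(g$edges)) return(character(0))
  la <- g$labels[g$edges[, 1]]
  lb <- g$labels[g$edges[, 2]]
  paste(pmin(la, lb), pmax(la, lb), sep = "~")
}

#' All label-preserving embeddings of a pattern into a graph
#'
#' Injective mappings of pattern nodes onto graph nodes that preserve node
#' labels and map every pattern edge onto a graph edge (subgraph
#' monomorphism; non-edges of the pattern are unconstrained).
#'
#' @param pattern,g `homst_graph` objects; the pattern must be connected.
#' @param max_embeddings Stop after this many embeddings (1 suffices for a
#'   containment test).
#' @return List of integer vectors, each mapping pattern node -> graph node.
#' @export
graph_embeddings <- function(pattern, g, max_embeddings = Inf) {
  if (pattern$n == 0) return(list(integer(0)))
  if (!graph_is_connected(pattern)) stop("pattern must be connected")
  # fast path: unique labels on both sides -> at most one candidate per node
  if (has_unique_labels(pattern) && has_unique_labels(g)) {
    map <- match(pattern$labels, g$labels)
    if (anyNA(map)) return(list())
    if (nrow(pattern$edges)) {
      gkeys <- edge_label_keys(g)
      if (!all(edge_label_keys(pattern) %in% gkeys)) return(list())
    }
    return(list(map))
  }
  padj <- adjacency_list(pattern)
  gadj <- adjacency_list(g)
  gadj_sets <- lapply(gadj, function(a) if (is.null(a)) integer(0) else a[, 1])
  # BFS order over pattern nodes so each new node has a mapped neighbor
  order_ <- integer(0); seen <- logical(pattern$n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_ <- c(order_, v)
    nb <- padj[[v]]
    if (!is.null(nb)) {
      new <- nb[!seen[nb[, 1]], 1]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  out <- list()
  map <- rep(NA_integer_, pattern$n)
  used <- logical(g$n)
  recurse <- function(pos) {
    if (length(out) >= max_embeddings) return()
    if (pos > length(order_)) {
      out[[length(out) + 1L]] <<- map
      return()
    }
    pv <- order_[pos]
    mapped_nb <- padj[[pv]]
    mapped_nb <- if (is.null(mapped_nb)) integer(0)
    else mapped_nb[!is.na(map[mapped_nb[, 1]]), 1]
    cand <- if (length(mapped_nb)) {
      Reduce(intersect, lapply(mapped_nb, function(u) gadj_sets[[map[u]]]))
    } else {
      seq_len(g$n)
    }
    cand <- cand[!used[cand] & g$labels[cand] == pattern$labels[pv]]
    for (gv in cand) {
      map[pv] <<- gv; used[gv] <<- TRUE
      recurse(pos + 1L)
      map[pv] <<- NA_integer_; used[gv] <<- FALSE
      if (length(out) >= max_embeddings) return()
    }
  }
  recurse(1L)
  out
}

#' Does a graph contain a connected pattern?
#'
#' Label-respecting subgraph containment. With unique node labels on both
#' sides this collapses to label-set plus edge-set inclusion; otherwise a
#' backtracking subgraph-monomorphism search is used.
#'
#' @inheritParams graph_embeddings
#' @return TRUE or FALSE.
#' @export
graph_contains <- function(g, pattern) {
  length(graph_embeddings(pattern, g, max_embeddings = 1)) > 0
}

#' Minimum DFS code of a connected labeled graph
#'
#' The canonical label used by gSpan: each DFS traversal of the graph spells
#' a code of edge 5-tuples `(t_from, t_to, label_from, label_edge, label_to)`
#' (edge labels are constant here); the minimum code under the DFS
#' lexicographic order identifies the graph up to isomorphism. Computed by
#' maintaining all partial traversals that can still realize the minimum and
#' extending them one minimal tuple at a time (backward extensions from the
#' rightmost vertex before forward extensions from the rightmost path).
#'
#' @param g A connected `homst_graph`.
#' @return List with `tuples` (data frame `from, to, label_from, label_to`,
#'   0-based times) and the collapsed `code` string. An edgeless graph yields
#'   its sorted label string.
#' @export
min_dfs_code <- function(g) {
  m <- nrow(g$edges)
  if (m == 0) {
    code <- paste0("V:", paste(sort(g$labels), collapse = ","))
    return(list(tuples = data.frame(from = integer(0), to = integer(0),
                                    label_from = character(0),
                                    label_to = character(0)),
                code = code))
  }
  if (!graph_is_connected(g)) stop("minimum DFS code requires a connected graph")
  adj <- adjacency_list(g)
  lab <- g$labels
  # initial tuple: minimal (label_from, label_to) over all edge orientations
  ori <- rbind(g$edges, g$edges[, 2:1, drop = FALSE])
  keys <- paste(lab[ori[, 1]], lab[ori[, 2]], sep = "\r")
  best <- min(keys)
  states <- list()
  for (r in which(keys == best)) {
    u <- ori[r, 1]; v <- ori[r, 2]
    eid <- edge_id_of(g, u, v)
    states[[length(states) + 1L]] <-
      list(map = c(u, v), used = eid, rmpath = c(1L, 2L))
  }
  tuples <- list(c(0L, 1L, lab[ori[keys == best, 1][1]],
                   lab[ori[keys == best, 2][1]]))
  while (length(tuples) < m + 0L && length(tuples) <= m) {
    if (length(tuples) == m) break
    cand <- list()  # each: list(state_idx, key, apply info)
    for (si in seq_along(states)) {
      st <- states[[si]]
      r <- length(st$map)
      vr <- st$map[r]
      rmpath <- st$rmpath
      parent_time <- if (length(rmpath) >= 2) rmpath[length(rmpath) - 1L] else NA_integer_
      # backward: rightmost vertex -> rightmost-path vertex (not its parent)
      for (t in rmpath[-length(rmpath)]) {
        if (!is.na(parent_time) && t == parent_time) next
        u <- st$map[t]
        eid <- edge_id_of(g, vr, u)
        if (!is.na(eid) && !(eid %in% st$used)) {
          cand[[length(cand) + 1L]] <- list(
            si = si, type = 0L, k1 = t, li = lab[vr], lj = lab[u],
            eid = eid, t = t)
        }
      }
      # forward: rightmost-path vertex -> unmapped neighbor
      for (pos in seq_along(rmpath)) {
        t <- rmpath[pos]
        u <- st$map[t]
        nb <- adj[[u]]
        if (is.null(nb)) next
        for (rw in seq_len(nrow(nb))) {
          w <- nb[rw, 1]; eid <- nb[rw, 2]
          if (w %in% st$map || eid %in% st$used) next
          cand[[length(cand) + 1L]] <- list(
            si = si, type = 1L, k1 = -t, li = lab[u], lj = lab[w],
            eid = eid, t = t, w = w, pos = pos)
        }
      }
    }
    if (!length(cand)) stop("internal error: stalled DFS-code search")
    ck <- vapply(cand, function(cc)
      sprintf("%d\r%08d\r%s\r%s", cc$type, cc$k1 + 10000L, cc$li, cc$lj), "")
    bestk <- min(ck)
    winners <- cand[ck == bestk]
    w1 <- winners[[1]]
    r_new <- length(states[[w1$si]]$map)
    if (w1$type == 0L) {
      tuples[[length(tuples) + 1L]] <- c(r_new - 1L, w1$t - 1L, w1$li, w1$lj)
    } else {
      tuples[[length(tuples) + 1L]] <- c(w1$t - 1L, r_new, w1$li, w1$lj)
    }
    new_states <- list()
    seen_keys <- character(0)
    for (cc in winners) {
      st <- states[[cc$si]]
      if (cc$type == 0L) {
        st$used <- c(st$used, cc$eid)
      } else {
        st$map <- c(st$map, cc$w)
        st$used <- c(st$used, cc$eid)
        st$rmpath <- c(st$rmpath[seq_len(cc$pos)], length(st$map))
      }
      sk <- paste(c(st$map, 0L, sort(st$used)), collapse = ",")
      if (!(sk %in% seen_keys)) {
        seen_keys <- c(seen_keys, sk)
        new_states[[length(new_states) + 1L]] <- st
      }
    }
    states <- new_states
  }
  tup <- do.call(rbind, tuples)
  tuples_df <- data.frame(from = as.integer(tup[, 1]), to = as.integer(tup[, 2]),
                          label_from = tup[, 3], label_to = tup[, 4],
                          stringsAsFactors = FALSE)
  code <- paste(sprintf("(%d,%d,%s,%s)", tuples_df$from, tuples_df$to,
                        tuples_df$label_from, tuples_df$label_to),
                collapse = "")
  list(tuples = tuples_df, code = code)
}

edge_id_of <- function(g, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  hit <- which(g$edges[, 1] == lo & g$edges[, 2] == hi)
  if (length(hit)) hit[1] else NA_integer_
}

#' Canonical key of a graph
#'
#' For graphs with unique node labels (the default pair-node identity
#' labeling) the graph is its edge set, so the key is the sorted edge-label
#' list; otherwise the minimum DFS code string.
#'
#' @param g A `homst_graph`.
#' @return Character scalar; equal keys iff isomorphic (label-preserving).
#' @export
graph_canonical_key <- function(g) {
  if (has_unique_labels(g)) {
    if (!nrow(g$edges)) return(paste0("V:", paste(sort(g$labels), collapse = ",")))
    paste0("E:", paste(sort(edge_label_keys(g)), collapse = ";"))
  } else {
    min_dfs_code(g)$code
  }
}
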