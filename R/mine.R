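#' Convert a spanning tree to an unweighted labeled graph
#'
#' Weights are dropped (patterns are mined on topology only). By default
#' nodes carry their pair-node identity labels so all subjects share a node
#' universe; `degree_labels = TRUE` substitutes the node degree as label.
#'
#' @param tree A `homst_tree`.
#' @param degree_labels Label nodes by degree instead of identity.
#' @return A [labeled_graph()].
#' @export
tree_to_graph <- function(tree, degree_labels = FALSE) {
  g <- labeled_graph(cbind(tree$edges$from, tree$edges$to), tree$node_labels)
  if (degree_labels) {
    deg <- tabulate(c(g$edges), nbins = g$n)
    g$labels <- as.character(deg)
  }
  g
}

#' Frequency of a subgraph pattern in a graph set
#'
#' Fraction of the graphs in `G` containing `g_s` as a (label-respecting)
#' subgraph.
#'
#' @param g_s Connected `homst_graph` pattern.
#' @param G Nonempty list of `homst_graph` objects.
#' @return Frequency in \[0, 1\].
#' @export
pattern_frequency <- function(g_s, G) {
  if (!length(G)) stop("graph set G must be nonempty")
  if (!graph_is_connected(g_s)) stop("pattern must be connected")
  mean(vapply(G, graph_contains, FALSE, pattern = g_s))
}

support_count <- function(min_fq, n) {
  # smallest count c with c/n >= min_fq (tolerant to representation error)
  ceiling(min_fq * n - 1e-9)
}

#' Mine frequent connected subgraphs (gSpan)
#'
#' Enumerates exactly the connected patterns whose frequency in `G` is at
#' least `min_fq`, each reported once under its canonical label. Patterns
#' grow one adjacent edge at a time (frequency is anti-monotone, so every
#' frequent pattern is reachable through frequent ancestors); candidates
#' already seen under their canonical key -- the sorted edge set for
#' identity-labeled graphs, the minimum DFS code otherwise -- are pruned.
#'
#' @param G List of `homst_graph` objects over a shared label alphabet.
#' @param min_fq Frequency threshold in (0, 1].
#' @param max_edges Safety cap on pattern size (edges); a message is emitted
#'   if the cap truncates the search. Default 10.
#' @return Object of class `homst_patterns`: list of patterns, each with
#'   fields `graph`, `key`, `n_edges`, `fq`.
#' @export
gspan_mine <- function(G, min_fq, max_edges = 10L) {
  if (!is.numeric(min_fq) || min_fq <= 0 || min_fq > 1)
    stop("min_fq must lie in (0, 1]")
  if (!length(G)) stop("graph set G must be nonempty")
  need <- support_count(min_fq, length(G))
  identity_mode <- all(vapply(G, has_unique_labels, FALSE))
  pats <- if (identity_mode) mine_identity(G, need, max_edges)
  else mine_general(G, need, max_edges)
  for (i in seq_along(pats)) pats[[i]]$fq <- pats[[i]]$support / length(G)
  structure(pats, class = "homst_patterns", n_graphs = length(G))
}

mine_identity <- function(G, need, max_edges) {
  nG <- length(G)
  keysets <- lapply(G, edge_label_keys)
  all_keys <- unique(unlist(keysets))
  key_in <- lapply(keysets, function(k) all_keys %in% k)  # per graph
  occ <- do.call(cbind, key_in)                            # keys x graphs
  rownames(occ) <- all_keys
  ends <- do.call(rbind, strsplit(all_keys, "~", fixed = TRUE))
  support1 <- rowSums(occ)
  out <- list()
  seen <- new.env(parent = emptyenv())
  capped <- FALSE
  grow <- function(keys, supp_ids) {
    canon <- paste(sort(keys), collapse = ";")
    if (!is.null(seen[[canon]])) return()
    seen[[canon]] <- TRUE
    out[[length(out) + 1L]] <<- list(
      graph = graph_from_label_pairs(ends[match(keys, all_keys), , drop = FALSE]),
      key = paste0("E:", canon), n_edges = length(keys),
      support = length(supp_ids))
    if (length(keys) >= max_edges) {
      capped <<- TRUE
      return()
    }
    labs <- unique(c(ends[match(keys, all_keys), ]))
    touch <- (ends[, 1] %in% labs | ends[, 2] %in% labs) &
      !(all_keys %in% keys) & support1 >= need
    for (k in all_keys[touch]) {
      new_supp <- supp_ids[occ[k, supp_ids]]
      if (length(new_supp) >= need) grow(c(keys, k), new_supp)
    }
  }
  for (k in all_keys[support1 >= need])
    grow(k, which(occ[k, ]))
  if (capped)
    message("gspan_mine: pattern size cap (", max_edges, " edges) reached; ",
            "larger frequent patterns were not enumerated")
  out
}

mine_general <- function(G, need, max_edges) {
  nG <- length(G)
  # frequent single edges as (label_from <= label_to) pairs
  epairs <- unique(do.call(rbind, lapply(G, function(g) {
    if (!nrow(g$edges)) return(NULL)
    la <- g$labels[g$edges[, 1]]; lb <- g$labels[g$edges[, 2]]
    unique(cbind(pmin(la, lb), pmax(la, lb)))
  })))
  out <- list()
  seen <- new.env(parent = emptyenv())
  capped <- FALSE
  grow <- function(pat, supp_ids) {
    canon <- graph_canonical_key(pat)
    if (!is.null(seen[[canon]])) return()
    seen[[canon]] <- TRUE
    out[[length(out) + 1L]] <<- list(graph = pat, key = canon,
                                     n_edges = nrow(pat$edges),
                                     support = length(supp_ids))
    if (nrow(pat$edges) >= max_edges) {
      capped <<- TRUE
      return()
    }
    # extensions observed in supporting graphs, translated to pattern level
    exts <- list()
    for (gi in supp_ids) {
      g <- G[[gi]]
      for (map in graph_embeddings(pat, g)) {
        inv <- rep(NA_integer_, g$n); inv[map] <- seq_len(pat$n)
        for (e in seq_len(nrow(g$edges))) {
          a <- g$edges[e, 1]; b <- g$edges[e, 2]
          pa <- inv[a]; pb <- inv[b]
          if (!is.na(pa) && !is.na(pb)) {
            if (is.na(edge_id_of(pat, pa, pb)))
              exts[[paste0("b", min(pa, pb), ",", max(pa, pb))]] <-
                list(type = "b", pa = min(pa, pb), pb = max(pa, pb))
          } else if (!is.na(pa) || !is.na(pb)) {
            anchor <- if (is.na(pa)) pb else pa
            newlab <- if (is.na(pa)) g$labels[a] else g$labels[b]
            exts[[paste0("f", anchor, ",", newlab)]] <-
              list(type = "f", anchor = anchor, newlab = newlab)
          }
        }
      }
    }
    for (ex in exts) {
      if (ex$type == "b") {
        new_pat <- labeled_graph(rbind(pat$edges, c(ex$pa, ex$pb)), pat$labels)
      } else {
        new_pat <- labeled_graph(rbind(pat$edges, c(ex$anchor, pat$n + 1L)),
                                 c(pat$labels, ex$newlab))
      }
      new_supp <- supp_ids[vapply(G[supp_ids], graph_contains, FALSE,
                                  pattern = new_pat)]
      if (length(new_supp) >= need) grow(new_pat, new_supp)
    }
  }
  if (!is.null(epairs)) {
    for (r in seq_len(nrow(epairs))) {
      # two distinct nodes even when the endpoint labels coincide
      pat <- labeled_graph(rbind(c(1L, 2L)), c(epairs[r, 1], epairs[r, 2]))
      supp <- which(vapply(G, graph_contains, FALSE, pattern = pat))
      if (length(supp) >= need) grow(pat, supp)
    }
  }
  if (capped)
    message("gspan_mine: pattern size cap (", max_edges, " edges) reached; ",
            "larger frequent patterns were not enumerated")
  out
}

#' Discriminative scores of candidate patterns
#'
#' Pools the patterns mined from the positive and negative groups (union by
#' canonical key), recomputes each pattern's frequency on both full graph
#' lists and scores it as `S = fq(g_s | G_pos) - fq(g_s | G_neg)`, so
#' `S = 1` marks a pattern present in every positive-group graph and absent
#' from all negative-group graphs, `S = -1` the mirrored case.
#'
#' @param pat_pos,pat_neg `homst_patterns` mined from each group (either may
#'   be an empty list).
#' @param G_pos,G_neg Nonempty lists of the groups' graphs.
#' @return Object of class `homst_scored`: list of patterns with fields
#'   `graph`, `key`, `n_edges`, `fq_pos`, `fq_neg`, `score`.
#' @export
discriminative_scores <- function(pat_pos, pat_neg, G_pos, G_neg) {
  if (!length(G_pos) || !length(G_neg)) stop("both graph lists must be nonempty")
  pool <- c(unclass(pat_pos), unclass(pat_neg))
  keys <- vapply(pool, `[[`, "", "key")
  pool <- pool[!duplicated(keys)]
  scored <- lapply(pool, function(p) {
    fp <- pattern_frequency(p$graph, G_pos)
    fn <- pattern_frequency(p$graph, G_neg)
    list(graph = p$graph, key = p$key, n_edges = p$n_edges,
         fq_pos = fp, fq_neg = fn, score = fp - fn)
  })
  structure(scored, class = "homst_scored")
}

#' Balanced top-k discriminative pattern selection
#'
#' Takes the k patterns with the highest positive scores and the k with the
#' most negative scores (2k in total). Ties are broken by larger pooled
#' frequency, then canonical key order. If a direction has fewer than k
#' candidates, the available ones are taken with a warning.
#'
#' @param scored A `homst_scored` list.
#' @param k Patterns to keep per direction.
#' @param n_pos,n_neg Group sizes used to pool frequencies for tie-breaking;
#'   defaults to equal weighting.
#' @return `homst_scored` list of at most 2k selected patterns (positive
#'   direction first).
#' @export
select_top_k <- function(scored, k, n_pos = 1L, n_neg = 1L) {
  sc <- vapply(scored, `[[`, 0, "score")
  pooled <- (vapply(scored, `[[`, 0, "fq_pos") * n_pos +
               vapply(scored, `[[`, 0, "fq_neg") * n_neg) / (n_pos + n_neg)
  keys <- vapply(scored, `[[`, "", "key")
  take <- function(side) {
    idx <- if (side > 0) which(sc > 0) else which(sc < 0)
    if (length(idx) < k)
      warning(sprintf("only %d of %d requested %s-direction patterns available",
                      length(idx), k, if (side > 0) "positive" else "negative"))
    ord <- order(if (side > 0) -sc[idx] else sc[idx], -pooled[idx], keys[idx])
    idx[ord][seq_len(min(k, length(idx)))]
  }
  structure(c(scored[take(1)], scored[take(-1)]), class = "homst_scored")
}

#' Pattern-restricted subject graph
#'
#' The subgraph of a subject's spanning tree induced by the union of the
#' edges of those selected patterns the subject actually contains; the input
#' to the graph kernel. May be empty when the subject contains no pattern.
#'
#' @param tree A `homst_tree` (or a `homst_graph` on the shared alphabet).
#' @param patterns A `homst_scored` or `homst_patterns` list.
#' @return A [labeled_graph()] (possibly with zero nodes).
#' @export
subject_pattern_graph <- function(tree, patterns) {
  g <- if (inherits(tree, "homst_tree")) tree_to_graph(tree) else tree
  pairs <- NULL
  for (p in patterns) {
    for (map in graph_embeddings(p$graph, g)) {
      if (nrow(p$graph$edges))
        pairs <- rbind(pairs, cbind(g$labels[map[p$graph$edges[, 1]]],
                                    g$labels[map[p$graph$edges[, 2]]]))
    }
  }
  if (is.null(pairs)) return(labeled_graph(NULL, character(0)))
  graph_from_label_pairs(pairs)
}
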