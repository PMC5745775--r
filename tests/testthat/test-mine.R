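path_graph <- function(labels) {
  n <- length(labels)
  labeled_graph(cbind(seq_len(n - 1), 2:n), labels)
}

test_that("pattern frequency is a direct containment count", {
  pat <- graph_from_label_pairs(rbind(c("a", "b")))
  G <- list(path_graph(c("a", "b", "c")),
            path_graph(c("b", "a", "d")),
            path_graph(c("c", "d", "e")),
            path_graph(c("a", "b", "d")))
  expect_equal(pattern_frequency(pat, G), 0.75)
  expect_equal(pattern_frequency(G[[1]], list(G[[1]])), 1)
  expect_error(pattern_frequency(pat, list()), "nonempty")
  disc <- labeled_graph(rbind(c(1, 2)), c("a", "b", "c"))
  expect_error(pattern_frequency(disc, G), "connected")
})

test_that("general containment agrees with the embedding enumeration", {
  set.seed(51)
  for (rep in 1:20) {
    g <- random_labeled_graph(6, sample(3:7, 1), c("x", "y"))
    pat <- random_labeled_graph(3, sample(1:3, 1), c("x", "y"))
    if (!homst:::graph_is_connected(pat)) next
    emb <- graph_embeddings(pat, g)
    expect_equal(graph_contains(g, pat), length(emb) > 0)
    for (map in emb) {
      expect_equal(g$labels[map], pat$labels)
      for (e in seq_len(nrow(pat$edges)))
        expect_true(!is.na(homst:::edge_id_of(g, map[pat$edges[e, 1]],
                                              map[pat$edges[e, 2]])))
    }
  }
})

test_that("minimum DFS codes canonicalize up to isomorphism", {
  set.seed(52)
  for (rep in 1:30) {
    g <- random_labeled_graph(sample(3:6, 1), sample(2:6, 1), c("p", "q", "r"))
    if (!homst:::graph_is_connected(g)) next
    perm <- sample(g$n)
    new_labels <- character(g$n)
    new_labels[perm] <- g$labels
    gp <- labeled_graph(cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]),
                        new_labels)
    expect_equal(min_dfs_code(gp)$code, min_dfs_code(g)$code)
  }
  # distinguishes non-isomorphic graphs exactly as the BLISS oracle does
  set.seed(53)
  graphs <- replicate(25, {
    g <- random_labeled_graph(4, sample(3:5, 1), c("p", "q"))
    if (homst:::graph_is_connected(g)) g else NULL
  }, simplify = FALSE)
  graphs <- Filter(Negate(is.null), graphs)
  codes <- vapply(graphs, function(g) min_dfs_code(g)$code, "")
  oracle <- vapply(graphs, oracle_canonical_key, "")
  for (i in seq_along(graphs)) for (j in seq_along(graphs))
    expect_equal(codes[i] == codes[j], oracle[i] == oracle[j])
})

test_that("mining three identical trees at min_fq 1 enumerates all connected subgraphs", {
  tree <- path_graph(c("A", "B", "C", "D"))
  G <- list(tree, tree, tree)
  pats <- gspan_mine(G, min_fq = 1)
  # independent enumeration: connected edge subsets of the path
  oracle <- oracle_frequent_patterns(G, 1)
  expect_equal(length(pats), length(oracle))
  expect_equal(length(pats), 6L)
  expect_true(all(vapply(pats, `[[`, 0, "fq") == 1))
  keys <- vapply(pats, function(p) oracle_canonical_key(p$graph), "")
  expect_setequal(keys, names(oracle))
})

test_that("graphs with disjoint label alphabets share no frequent pattern", {
  G <- list(path_graph(c("a", "b", "c")), path_graph(c("x", "y", "z")))
  expect_length(gspan_mine(G, min_fq = 1), 0L)
  expect_error(gspan_mine(G, min_fq = 0), "min_fq")
  expect_error(gspan_mine(list(), 0.5), "nonempty")
})

test_that("identity-label mining matches brute-force enumeration", {
  set.seed(54)
  for (rep in 1:10) {
    nG <- sample(3:5, 1)
    G <- replicate(nG, {
      n <- sample(4:6, 1)
      g <- random_labeled_graph(n, sample(2:7, 1), as.character(1:9))
      g$labels <- as.character(sample(9, n))  # identity labels: all distinct
      g
    }, simplify = FALSE)
    min_fq <- sample(c(0.4, 0.6, 1), 1)
    pats <- gspan_mine(G, min_fq)
    oracle <- oracle_frequent_patterns(G, min_fq)
    got <- vapply(pats, function(p) oracle_canonical_key(p$graph), "")
    expect_setequal(got, names(oracle))
    expect_equal(vapply(pats, `[[`, 0, "fq")[order(got)],
                 unname(oracle[sort(got)]))
  }
})

test_that("general-label mining matches brute-force enumeration", {
  set.seed(55)
  for (rep in 1:8) {
    nG <- sample(3:4, 1)
    G <- replicate(nG,
      random_labeled_graph(sample(4:5, 1), sample(2:6, 1), c("u", "v")),
      simplify = FALSE)
    min_fq <- sample(c(0.5, 1), 1)
    pats <- gspan_mine(G, min_fq)
    oracle <- oracle_frequent_patterns(G, min_fq)
    got <- vapply(pats, function(p) oracle_canonical_key(p$graph), "")
    expect_setequal(got, names(oracle))
    expect_equal(vapply(pats, `[[`, 0, "fq")[order(got)],
                 unname(oracle[sort(got)]))
  }
})

test_that("mining output is invariant to graph order and satisfies anti-monotonicity", {
  set.seed(56)
  G <- replicate(4, {
    n <- 5
    g <- random_labeled_graph(n, sample(3:6, 1), as.character(1:9))
    g$labels <- as.character(sample(9, n))
    g
  }, simplify = FALSE)
  pats <- gspan_mine(G, 0.5)
  pats_rev <- gspan_mine(rev(G), 0.5)
  key_fq <- function(ps) {
    k <- vapply(ps, `[[`, "", "key")
    stats::setNames(vapply(ps, `[[`, 0, "fq")[order(k)], sort(k))
  }
  expect_equal(key_fq(pats), key_fq(pats_rev))
  # every connected sub-pattern of a frequent pattern is itself frequent
  keys <- vapply(pats, `[[`, "", "key")
  for (p in pats) {
    m <- nrow(p$graph$edges)
    if (m < 2) next
    for (drop in seq_len(m)) {
      sub <- subgraph_from_edge_subset(p$graph, setdiff(seq_len(m), drop))
      if (homst:::graph_is_connected(sub))
        expect_true(graph_canonical_key(sub) %in% keys)
    }
  }
})

test_that("discriminative scores hit the +/-1 bounds and are antisymmetric", {
  pat <- graph_from_label_pairs(rbind(c("a", "b"), c("b", "c")))
  with_pat <- lapply(1:4, function(i)
    graph_from_label_pairs(rbind(c("a", "b"), c("b", "c"),
                                 c("c", paste0("z", i)))))
  without <- lapply(1:4, function(i)
    path_graph(paste0(c("p", "q", "r"), i)))
  mined_pos <- gspan_mine(with_pat, 1)
  sc <- discriminative_scores(mined_pos, list(), with_pat, without)
  s_pat <- vapply(sc, `[[`, 0, "score")[
    vapply(sc, `[[`, "", "key") == graph_canonical_key(pat)]
  expect_equal(s_pat, 1)
  # mirrored construction scores exactly -1
  sc_m <- discriminative_scores(list(), mined_pos, without, with_pat)
  s_m <- vapply(sc_m, `[[`, 0, "score")[
    vapply(sc_m, `[[`, "", "key") == graph_canonical_key(pat)]
  expect_equal(s_m, -1)
  # swapping groups negates every score
  expect_equal(vapply(sc, `[[`, 0, "score"), -vapply(sc_m, `[[`, 0, "score"))
  # equal frequencies give score 0
  sc0 <- discriminative_scores(mined_pos, list(), with_pat, with_pat)
  expect_true(all(vapply(sc0, `[[`, 0, "score") == 0))
  expect_true(all(abs(vapply(sc, `[[`, 0, "score")) <= 1))
})

test_that("balanced top-k keeps the score extremes deterministically", {
  mk <- function(key, score) list(graph = graph_from_label_pairs(
    rbind(c(key, paste0(key, "x")))), key = key, n_edges = 1L,
    fq_pos = max(score, 0), fq_neg = max(-score, 0), score = score)
  scored <- structure(list(mk("a", 0.9), mk("b", 0.5), mk("c", -0.4),
                           mk("d", -0.8)), class = "homst_scored")
  top <- select_top_k(scored, 1)
  expect_equal(vapply(top, `[[`, "", "key"), c("a", "d"))
  # shortfall warns (both directions here) and returns what exists
  expect_warning(expect_warning(res <- select_top_k(scored, 3), "of 3"))
  expect_length(res, 4L)
  # all-zero scores: nothing qualifies for either direction, deterministically
  zeros <- structure(lapply(list("a", "b"), mk, score = 0),
                     class = "homst_scored")
  z1 <- suppressWarnings(select_top_k(zeros, 1))
  z2 <- suppressWarnings(select_top_k(zeros, 1))
  expect_identical(z1, z2)
  expect_length(z1, 0L)
})

test_that("subject pattern graphs are the union of contained pattern edges", {
  tree <- structure(list(n = 4,
                         edges = data.frame(from = c(1L, 2L, 2L),
                                            to = c(2L, 3L, 4L),
                                            weight = c(0.9, 0.8, 0.7)),
                         node_labels = c("A", "B", "C", "D")),
                    class = "homst_tree")
  pat_in <- list(graph = graph_from_label_pairs(rbind(c("A", "B"))),
                 key = "k1", n_edges = 1L)
  pat_in2 <- list(graph = graph_from_label_pairs(rbind(c("B", "C"))),
                  key = "k2", n_edges = 1L)
  pat_out <- list(graph = graph_from_label_pairs(rbind(c("C", "D"))),
                  key = "k3", n_edges = 1L)
  sg <- subject_pattern_graph(tree, list(pat_in, pat_in2, pat_out))
  expect_setequal(homst:::edge_label_keys(sg), c("A~B", "B~C"))
  # no contained pattern -> empty graph
  none <- list(graph = graph_from_label_pairs(rbind(c("X", "Y"))),
               key = "k", n_edges = 1L)
  empty <- subject_pattern_graph(tree, list(none))
  expect_equal(empty$n, 0L)
  # subject tree identical to a pattern returns the whole pattern
  whole <- list(graph = tree_to_graph(tree), key = "w", n_edges = 3L)
  sg_whole <- subject_pattern_graph(tree, list(whole))
  expect_setequal(homst:::edge_label_keys(sg_whole),
                  homst:::edge_label_keys(tree_to_graph(tree)))
  # random case: union of per-pattern brute-force matches
  set.seed(57)
  g <- tree_to_graph(tree)
  pats <- list(pat_in, pat_out, whole)
  manual <- unique(unlist(lapply(pats, function(p)
    if (graph_contains(g, p$graph)) homst:::edge_label_keys(p$graph))))
  expect_setequal(homst:::edge_label_keys(subject_pattern_graph(tree, pats)),
                  manual)
})
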