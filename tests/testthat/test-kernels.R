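edge_graph <- function(a, b) graph_from_label_pairs(rbind(c(a, b)))

test_that("WL kernel matches a hand-traced single-edge case", {
  g1 <- edge_graph("A", "B")
  g2 <- edge_graph("A", "B")
  # iteration 0: labels {A,B} in both -> dot product 2; k(x,x) = 2 as well.
  # iteration 1: refined labels (A|B) and (B|A) match across the identical
  # graphs -> adds 2. Total with h = 1: 4.
  K <- wl_subtree_kernel(list(g1, g2), h = 1)
  expect_equal(K[1, 2], 4)
  expect_equal(K[1, 1], K[1, 2])  # identical graphs: k(x,y) = k(x,x)
  # a graph sharing only one label at iteration 0 and nothing refined
  g3 <- edge_graph("A", "C")
  K2 <- wl_subtree_kernel(list(g1, g3), h = 1)
  expect_equal(K2[1, 2], 1)
  # an empty graph shares nothing with a nonempty one, but two empty
  # graphs are identical objects (virtual empty-state node)
  empty <- labeled_graph(NULL, character(0))
  K3 <- wl_subtree_kernel(list(g1, empty, empty), h = 2)
  expect_equal(K3[1, 2], 0)
  expect_gt(K3[2, 2], 0)
  expect_equal(K3[2, 3], K3[2, 2])
  expect_equal(normalize_kernel(K3)[2, 3], 1)
})

test_that("WL kernel at h = 0 counts shared node labels", {
  set.seed(61)
  graphs <- replicate(4, {
    n <- sample(3:6, 1)
    random_labeled_graph(n, sample(2:5, 1), c("a", "b", "c"))
  }, simplify = FALSE)
  K <- wl_subtree_kernel(graphs, h = 0)
  for (i in 1:4) for (j in 1:4) {
    t1 <- table(graphs[[i]]$labels)
    t2 <- table(graphs[[j]]$labels)
    shared <- intersect(names(t1), names(t2))
    expect_equal(K[i, j], sum(as.numeric(t1[shared]) * as.numeric(t2[shared])))
  }
})

test_that("WL kernel is invariant to node order and is PSD", {
  set.seed(62)
  g <- random_labeled_graph(6, 7, c("a", "b"))
  perm <- sample(6)
  new_labels <- character(6); new_labels[perm] <- g$labels
  gp <- labeled_graph(cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]),
                      new_labels)
  K <- wl_subtree_kernel(list(g, gp), h = 3)
  expect_equal(K[1, 2], K[1, 1])
  graphs <- replicate(6, random_labeled_graph(5, 5, c("a", "b", "c")),
                      simplify = FALSE)
  Kr <- wl_subtree_kernel(graphs, h = 3)
  expect_equal(Kr, t(Kr))
  expect_gt(min(eigen(Kr, only.values = TRUE)$values), -1e-8)
})

test_that("vector kernel reproduces hand-computed Gram matrices", {
  fm <- rbind(c(1, 0), c(0, 1), c(1, 1))
  colnames(fm) <- c("f1", "f2")
  # bypass standardization to check the raw inner products
  K <- vector_kernel(fm, center = c(0, 0), scale = c(1, 1))
  expect_equal(K, rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 2)),
               ignore_attr = TRUE)
  expect_equal(K[1, 1], sum(fm[1, ]^2))
  expect_equal(K[1, 2], 0)  # orthogonal rows
  # default standardization centers and scales by column statistics
  set.seed(63)
  fm2 <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("g", 1:4)))
  K2 <- vector_kernel(fm2)
  Z <- scale(fm2)
  expect_equal(K2, tcrossprod(Z), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(vector_kernel(fm2[, 0]), "graph kernel")
})

test_that("kernel normalization forces a unit diagonal and is idempotent", {
  raw <- rbind(c(4, 2), c(2, 1))
  expect_equal(normalize_kernel(raw), matrix(1, 2, 2))
  expect_equal(normalize_kernel(rbind(c(4, 0), c(0, 9))), diag(2))
  set.seed(64)
  A <- matrix(rnorm(25), 5)
  K <- crossprod(A)
  Kn <- normalize_kernel(K)
  expect_equal(diag(Kn), rep(1, 5))
  expect_true(all(abs(Kn) <= 1 + 1e-12))
  expect_equal(normalize_kernel(Kn), Kn, tolerance = 1e-12)
  # zero-diagonal subject: row/column zeroed with a warning
  K0 <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 4))
  expect_warning(Kz <- normalize_kernel(K0), "zeroed")
  expect_equal(diag(Kz), rep(1, 3))
  expect_equal(Kz[2, c(1, 3)], c(0, 0))
})

test_that("convex kernel combination is entrywise and guarded", {
  K1 <- normalize_kernel(rbind(c(2, 1), c(1, 2)))
  K2 <- diag(2)
  expect_equal(combine_kernels(list(K1, K2), c(1, 0)), K1)
  expect_equal(combine_kernels(list(K1, K1), c(0.3, 0.7)), K1)
  got <- combine_kernels(list(K1, K2), c(0.4, 0.6))
  expect_equal(got, 0.4 * K1 + 0.6 * K2)
  expect_error(combine_kernels(list(K1, K2), c(0.5, 0.6)), "sum to 1")
  expect_error(combine_kernels(list(K1, diag(3)), c(0.5, 0.5)), "dimensions")
  expect_error(combine_kernels(list(2 * K1, K2), c(0.5, 0.5)), "normalized")
  # convex combinations of PSD matrices stay PSD
  set.seed(65)
  mats <- replicate(3, {
    A <- matrix(rnorm(16), 4)
    normalize_kernel(crossprod(A) + diag(4) * 0.1)
  }, simplify = FALSE)
  w <- c(0.2, 0.3, 0.5)
  comb <- combine_kernels(mats, w)
  expect_gt(min(eigen(comb, only.values = TRUE)$values), -1e-8)
})
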