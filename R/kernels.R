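#' Weisfeiler-Lehman subtree kernel
#'
#' `k(x, y)` sums, over refinement iterations 0..h, the inner products of the
#' graphs' compressed-label count vectors. At each iteration a node's new
#' label is the compression of its previous label concatenated with the
#' sorted multiset of its neighbors' labels; compression uses a deterministic
#' dictionary filled in first-seen order over the graphs as given, so kernel
#' values are reproducible. Refinement stops early once it no longer splits
#' any label class.
#'
#' An empty graph (a subject containing no pattern) is represented by a
#' single virtual node with a reserved label: two empty graphs are identical
#' objects and get maximal normalized similarity, while an empty and a
#' nonempty graph share nothing and get 0. Treating empty graphs as zero
#' vectors instead would zero their kernel rows and reduce their
#' classification to the majority-class bias term, which under leave-one-out
#' is systematically the wrong class.
#'
#' @param graphs List of `homst_graph` objects on a shared label alphabet.
#' @param h Maximum refinement iterations (h >= 0). Default 3.
#' @param degree_init Ignore stored labels and initialize each node's label
#'   with its degree (the rule for unlabeled graphs). Default FALSE.
#' @return Raw (unnormalized) symmetric PSD kernel matrix.
#' @export
wl_subtree_kernel <- function(graphs, h = 3L, degree_init = FALSE) {
  stopifnot(h >= 0)
  n <- length(graphs)
  graphs <- lapply(graphs, function(g) {
    if (g$n == 0) labeled_graph(NULL, "∅") else g
  })
  K <- matrix(0, n, n)
  adj <- lapply(graphs, function(g) {
    a <- adjacency_list(g)
    lapply(a, function(x) if (is.null(x)) integer(0) else x[, 1])
  })
  cur <- lapply(graphs, function(g) {
    if (degree_init) as.character(tabulate(c(g$edges), nbins = g$n))
    else g$labels
  })
  compress <- function(labs_by_graph) {
    dict <- new.env(parent = emptyenv())
    nxt <- 0L
    lapply(labs_by_graph, function(labs) {
      vapply(labs, function(l) {
        id <- dict[[l]]
        if (is.null(id)) {
          nxt <<- nxt + 1L
          assign(l, nxt, envir = dict)
          id <- nxt
        }
        id
      }, 0L, USE.NAMES = FALSE)
    })
  }
  ids <- compress(cur)
  n_classes <- 0L
  for (it in 0:h) {
    n_ids <- max(c(0L, unlist(ids)))
    if (n_ids > 0) {
      counts <- matrix(0, n, n_ids)
      for (g in seq_len(n)) {
        tb <- tabulate(ids[[g]], nbins = n_ids)
        counts[g, ] <- tb
      }
      K <- K + tcrossprod(counts)
    }
    if (it == h) break
    if (n_ids == n_classes) break  # refinement stabilized
    n_classes <- n_ids
    cur <- lapply(seq_len(n), function(g) {
      labs <- ids[[g]]
      vapply(seq_along(labs), function(v) {
        nb <- sort(labs[adj[[g]][[v]]])
        paste(labs[v], paste(nb, collapse = "."), sep = "|")
      }, "", USE.NAMES = FALSE)
    })
    ids <- compress(cur)
  }
  K
}

#' Linear kernel on selected feature vectors
#'
#' Standardizes each feature (training-set mean and standard deviation, or
#' the supplied ones) and returns the Gram matrix of inner products.
#' Constant features contribute zero after centering.
#'
#' @param fm Subjects-by-features matrix restricted to the selected features;
#'   at least one column is required.
#' @param center,scale Optional per-feature statistics (e.g., from the
#'   training rows); computed from `fm` when NULL.
#' @return Raw symmetric PSD kernel matrix with attributes `center`, `scale`.
#' @export
vector_kernel <- function(fm, center = NULL, scale = NULL) {
  if (!is.matrix(fm) || ncol(fm) == 0)
    stop("no selected features: fall back to the graph kernel alone")
  if (is.null(center)) center <- colMeans(fm)
  if (is.null(scale)) {
    scale <- apply(fm, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  Z <- sweep(sweep(fm, 2, center), 2, scale, "/")
  K <- tcrossprod(Z)
  attr(K, "center") <- center
  attr(K, "scale") <- scale
  K
}

#' Normalize a kernel matrix to unit diagonal
#'
#' `k*(x, y) = k(x, y) / sqrt(k(x, x) k(y, y))`. A subject with
#' `k(x, x) = 0` (e.g., an empty pattern graph under the WL kernel) gets a
#' unit diagonal and zero off-diagonal entries, with a warning. Idempotent.
#'
#' @param K Raw symmetric kernel matrix.
#' @return Normalized kernel: diagonal exactly 1, entries in \[-1, 1\].
#' @export
normalize_kernel <- function(K) {
  d <- diag(K)
  if (any(d < 0)) stop("kernel diagonal must be nonnegative")
  zero <- d == 0
  if (any(zero)) {
    warning(sum(zero), " subject(s) with k(x,x) = 0; their kernel rows were zeroed")
    d[zero] <- 1
  }
  Kn <- K / sqrt(outer(d, d))
  if (any(zero)) {
    Kn[zero, ] <- 0
    Kn[, zero] <- 0
  }
  diag(Kn) <- 1
  (Kn + t(Kn)) / 2
}

#' Convex combination of normalized kernels
#'
#' Entrywise weighted sum with nonnegative weights on the probability
#' simplex (`sum(a) = 1` to within 1e-12).
#'
#' @param kernels List of normalized kernel matrices of equal dimension.
#' @param weights Nonnegative weights summing to 1, one per kernel.
#' @return Combined kernel matrix.
#' @export
combine_kernels <- function(kernels, weights) {
  if (length(kernels) != length(weights)) stop("one weight per kernel required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be nonnegative and sum to 1")
  dims <- vapply(kernels, nrow, 0L)
  if (length(unique(dims)) != 1 ||
      any(vapply(kernels, ncol, 0L) != dims[1]))
    stop("kernel dimensions differ")
  if (any(vapply(kernels, function(K) max(abs(diag(K) - 1)), 0) > 1e-8))
    stop("kernels must be normalized (unit diagonal) before combination")
  out <- matrix(0, dims[1], dims[1])
  for (i in seq_along(kernels)) out <- out + weights[i] * kernels[[i]]
  out
}
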