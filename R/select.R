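#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the p-value from the asymptotic KS
#' distribution (the default; set `exact = TRUE` for the small-sample exact
#' computation).
#'
#' @param a,b Numeric samples, each of size at least 2.
#' @param exact Use the exact null distribution instead of the asymptotic one.
#' @return List with elements `D` and `p`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("both samples need size >= 2")
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Benjamini-Hochberg step-up selection
#'
#' Rejects the hypotheses with `p <= p_(k*)`, `k* = max{k : p_(k) <= k q / m}`
#' (equivalently, BH-adjusted p-value at most `q`).
#'
#' @param pvals Vector of p-values in \[0, 1\].
#' @param q False discovery rate level. Default 0.05.
#' @return Logical rejection mask aligned with `pvals`.
#' @export
bh_select <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Select discriminating features by KS + BH
#'
#' Per feature, a two-sample KS test between the class-0 and class-1 rows of
#' the feature matrix; the p-value vector is then thresholded by the
#' Benjamini-Hochberg procedure at level `q`. A feature constant in both
#' groups gets D = 0 and is never selected.
#'
#' @param fm Subjects-by-features numeric matrix with unique column names.
#' @param labels 0/1 class labels, one per row of `fm`.
#' @param q FDR level for [bh_select()]. Default 0.05.
#' @param exact Passed to [ks_two_sample()].
#' @return Object of class `homst_selection`: data frame `table`
#'   (`feature, D, p, selected`) and logical `mask`.
#' @export
select_features <- function(fm, labels, q = 0.05, exact = FALSE) {
  stopifnot(is.matrix(fm), nrow(fm) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2) stop("both classes must be present")
  a_rows <- labels == 0L
  D <- numeric(ncol(fm)); p <- numeric(ncol(fm))
  for (f in seq_len(ncol(fm))) {
    ks <- ks_two_sample(fm[a_rows, f], fm[!a_rows, f], exact = exact)
    D[f] <- ks$D; p[f] <- ks$p
  }
  mask <- bh_select(p, q) & p < 0.05
  names(mask) <- colnames(fm)
  tab <- data.frame(feature = colnames(fm), D = D, p = p,
                    selected = unname(mask), stringsAsFactors = FALSE)
  structure(list(table = tab, mask = mask, q = q), class = "homst_selection")
}

#' Nodes abnormal in at least two tree metrics
#'
#' Applies the reporting rule used for abnormal-connectivity tables: a
#' pair-node is reported when at least two of its three local metrics
#' (degree, eccentricity, betweenness) survive BH selection. Feature columns
#' are expected to be named `"n<q>_<metric>"` as produced by
#' [extract_features()].
#'
#' @param sel A `homst_selection` over the three-metric feature matrix.
#' @param pairs Optional [pair_index()] data frame to decode pair-nodes into
#'   ROI pairs.
#' @param roi_names Optional character vector of ROI names for decoding.
#' @return Data frame: one row per reported node with per-metric p-values and
#'   the count of significant metrics; zero rows when nothing passes.
#' @export
abnormal_nodes <- function(sel, pairs = NULL, roi_names = NULL) {
  tab <- sel$table
  m <- regmatches(tab$feature, regexec("^n([0-9]+)_([a-z]+)$", tab$feature))
  node <- as.integer(vapply(m, `[`, "", 2))
  metric <- vapply(m, `[`, "", 3)
  if (anyNA(node)) stop("feature names must look like 'n<q>_<metric>'")
  nodes <- sort(unique(node))
  rows <- lapply(nodes, function(q) {
    sub <- tab[node == q, ]
    met <- metric[node == q]
    n_sig <- sum(sub$selected)
    if (n_sig < 2) return(NULL)
    out <- data.frame(node = q, n_significant = n_sig)
    for (mm in c("degree", "eccentricity", "betweenness"))
      out[[paste0("p_", mm)]] <- if (mm %in% met) sub$p[met == mm] else NA_real_
    out
  })
  rows <- Filter(Negate(is.null), rows)
  rep_tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(node = integer(0), n_significant = integer(0),
                  p_degree = numeric(0), p_eccentricity = numeric(0),
                  p_betweenness = numeric(0))
  if (!is.null(pairs) && nrow(rep_tab)) {
    rep_tab$roi_i <- pairs$i[match(rep_tab$node, pairs$q)]
    rep_tab$roi_j <- pairs$j[match(rep_tab$node, pairs$q)]
    if (!is.null(roi_names)) {
      rep_tab$roi_i_name <- roi_names[rep_tab$roi_i]
      rep_tab$roi_j_name <- roi_names[rep_tab$roi_j]
    }
  }
  rep_tab
}

#' Relief feature weights
#'
#' Classic two-class Relief: for each sampled instance, each feature weight is
#' updated by `|x_f - nearmiss_f| - |x_f - nearhit_f|`, with the nearest hit
#' and miss found by Euclidean distance over all features (ties broken toward
#' the lower subject index). By default every subject is visited once in
#' order, making the result deterministic; with `n_iterations` below the
#' subject count, instances are sampled without replacement under `seed`.
#'
#' @param fm Subjects-by-features numeric matrix.
#' @param labels 0/1 class labels; each class needs at least 2 members.
#' @param n_iterations Number of sampled instances; default all subjects.
#' @param seed RNG seed used only when sampling.
#' @return List with per-feature `weights` and their `mean_weight`.
#' @export
relief_weights <- function(fm, labels, n_iterations = NULL, seed = 1L) {
  stopifnot(is.matrix(fm), nrow(fm) == length(labels))
  labels <- as.integer(labels)
  if (any(table(labels) < 2) || length(unique(labels)) != 2)
    stop("each class needs at least 2 members")
  n <- nrow(fm)
  idx <- seq_len(n)
  if (!is.null(n_iterations) && n_iterations < n) {
    set.seed(seed)
    idx <- sample(n, n_iterations)
  }
  w <- numeric(ncol(fm))
  for (s in idx) {
    d2 <- colSums((t(fm) - fm[s, ])^2)
    d2[s] <- Inf
    same <- labels == labels[s]
    hit <- which(same & seq_len(n) != s)[which.min(d2[same & seq_len(n) != s])]
    miss <- which(!same)[which.min(d2[!same])]
    w <- w + abs(fm[s, ] - fm[miss, ]) - abs(fm[s, ] - fm[hit, ])
  }
  w <- w / length(idx)
  names(w) <- colnames(fm)
  list(weights = w, mean_weight = mean(w))
}
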