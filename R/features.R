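#' Per-subject high-order trees and local tree features
#'
#' Runs, for every subject: sliding windows, low-order correlation stack,
#' pair-correlation series, high-order network, strongest-weight spanning
#' tree, and the three local tree metrics. The feature matrix has one column
#' per (pair-node, metric), named `"n<q>_<metric>"`.
#'
#' @param cohort List of `homst_subject` objects.
#' @param N,S Sliding-window length and step (see [make_windows()]).
#' @param abs_weights Passed to [kruskal_strongest_tree()].
#' @return Object of class `homst_features`: fields `fm` (subjects x 3P
#'   matrix), `trees` (list of `homst_tree`), `labels`, `subject_ids`,
#'   `pair_index`, `scheme`.
#' @export
extract_features <- function(cohort, N = 90L, S = 1L, abs_weights = FALSE) {
  stopifnot(length(cohort) >= 1)
  M <- ncol(cohort[[1]]$series)
  scheme <- make_windows(M, N, S)
  R <- nrow(cohort[[1]]$series)
  pairs <- pair_index(R)
  P <- nrow(pairs)
  metrics <- c("degree", "eccentricity", "betweenness")
  fm <- matrix(NA_real_, length(cohort), 3L * P)
  colnames(fm) <- as.vector(t(outer(paste0("n", seq_len(P), "_"), metrics,
                                    paste0)))
  trees <- vector("list", length(cohort))
  for (s in seq_along(cohort)) {
    H <- high_order(stack_correlation_series(
      windowed_low_order(cohort[[s]], scheme)))
    tree <- kruskal_strongest_tree(H, node_labels = rownames(H),
                                   abs_weights = abs_weights)
    mt <- tree_metrics(tree)
    fm[s, ] <- as.vector(t(as.matrix(mt[, metrics])))
    trees[[s]] <- tree
  }
  structure(list(fm = fm, trees = trees,
                 labels = vapply(cohort, `[[`, 0L, "label"),
                 subject_ids = vapply(cohort, `[[`, "", "subject_id"),
                 pair_index = pairs, scheme = scheme),
            class = "homst_features")
}
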