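#' Evaluation protocol for multikernel classification
#'
#' @param a_grid Grid for the vector-kernel weight `a` (graph kernel gets
#'   `1 - a`); default 0, 0.1, ..., 1.0.
#' @param cost_grid SVM soft-margin cost grid. Default `c(0.1, 1, 10, 100)`.
#' @param inner_folds Folds of the inner grid-search CV. Default 5.
#' @param q FDR level for in-fold feature selection. Default 0.05.
#' @param fq_pos,fq_neg Mining frequency thresholds for the positive (label
#'   1) and negative group. Defaults 0.286 and 0.211.
#' @param k_patterns Patterns kept per score direction. Default 10.
#' @param wl_h WL refinement iterations. Default 3.
#' @param max_pattern_edges Mining size cap. Default 10.
#' @param whole_sample_selection If TRUE, feature selection, mining and kernels are
#'   computed once on the whole sample and only the classifier is
#'   cross-validated -- the optimistic whole-sample protocol; the default
#'   FALSE redoes selection and mining inside every training fold.
#' @param seed Seed for inner-fold assignment.
#' @return Object of class `homst_protocol`.
#' @export
eval_protocol <- function(a_grid = seq(0, 1, by = 0.1),
                          cost_grid = c(0.1, 1, 10, 100),
                          inner_folds = 5L, q = 0.05,
                          fq_pos = 0.286, fq_neg = 0.211,
                          k_patterns = 10L, wl_h = 3L,
                          max_pattern_edges = 10L,
                          whole_sample_selection = FALSE, seed = 1L) {
  if (!length(a_grid) || any(a_grid < 0 | a_grid > 1))
    stop("a_grid must be a nonempty subset of [0, 1]")
  if (!length(cost_grid) || any(cost_grid <= 0))
    stop("cost_grid must contain positive costs")
  structure(list(a_grid = a_grid, cost_grid = cost_grid,
                 inner_folds = as.integer(inner_folds), q = q,
                 fq_pos = fq_pos, fq_neg = fq_neg,
                 k_patterns = as.integer(k_patterns), wl_h = as.integer(wl_h),
                 max_pattern_edges = as.integer(max_pattern_edges),
                 whole_sample_selection = isTRUE(whole_sample_selection), seed = as.integer(seed)),
            class = "homst_protocol")
}

#' Train a multikernel SVM on precomputed kernels
#'
#' Fits a soft-margin SVM on the convex combination of normalized kernel
#' matrices restricted to the training subjects. Decision scores are
#' oriented so that larger values indicate the positive class (label 1).
#'
#' @param kernels List of normalized kernel matrices over the training
#'   subjects.
#' @param labels 0/1 training labels (1 = positive class).
#' @param weights Convex combination weights, one per kernel.
#' @param cost SVM cost parameter. Default 1.
#' @return Object of class `homst_mksvm`.
#' @export
train_mksvm <- function(kernels, labels, weights, cost = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2)
    stop("training fold must contain both classes")
  K <- combine_kernels(kernels, weights)
  y <- factor(labels, levels = c(0L, 1L))
  # inverse-frequency class weights: without them, near-uninformative kernels
  # make leave-one-out folds vote the training majority, i.e. always the
  # class opposite to the held-out subject
  cw <- length(labels) / (2 * table(y))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                       C = cost, scaled = FALSE,
                       class.weights = stats::setNames(as.numeric(cw),
                                                       names(cw)))
  sv <- kernlab::SVindex(fit)
  dtr <- as.numeric(kernlab::predict(
    fit, kernlab::as.kernelMatrix(K[, sv, drop = FALSE]), type = "decision"))
  orient <- if (mean(dtr[labels == 1L]) >= mean(dtr[labels == 0L])) 1 else -1
  structure(list(fit = fit, sv = sv, weights = weights, cost = cost,
                 orient = orient, n_train = length(labels)),
            class = "homst_mksvm")
}

#' Decision scores of a multikernel SVM
#'
#' @param object A `homst_mksvm`.
#' @param newdata List of kernel blocks (one per trained kernel), each
#'   `n_test x n_train`, rows = test subjects, columns = the training
#'   subjects in training order.
#' @param ... Unused.
#' @return Numeric decision scores; positive favors class 1.
#' @export
predict.homst_mksvm <- function(object, newdata, ...) {
  blocks <- newdata
  if (is.matrix(blocks)) blocks <- list(blocks)
  if (length(blocks) != length(object$weights))
    stop("one kernel block per trained kernel required")
  Kt <- matrix(0, nrow(blocks[[1]]), object$n_train)
  for (i in seq_along(blocks)) Kt <- Kt + object$weights[i] * blocks[[i]]
  d <- as.numeric(kernlab::predict(
    object$fit, kernlab::as.kernelMatrix(Kt[, object$sv, drop = FALSE]),
    type = "decision"))
  object$orient * d
}

#' Classification report: confusion metrics and ROC/AUC
#'
#' Confusion counts at decision threshold 0 (scores are signed SVM decision
#' values); the ROC is swept over the unique score thresholds and the AUC is
#' its trapezoidal area, which equals the Mann-Whitney statistic with ties
#' counted half.
#'
#' @param truth 0/1 true labels; both classes must occur.
#' @param scores Finite decision scores, larger = more positive.
#' @param threshold Decision threshold. Default 0.
#' @return Object of class `homst_report`: accuracy, sensitivity,
#'   specificity, auc, confusion counts, and the ROC point table.
#' @export
report_metrics <- function(truth, scores, threshold = 0) {
  truth <- as.integer(truth)
  if (length(unique(truth)) != 2)
    stop("AUC is undefined with a single class in the truth")
  if (any(!is.finite(scores))) stop("scores must be finite")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[truth == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[truth == 0] >= t), 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(accuracy = (tp + tn) / length(truth),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 auc = auc,
                 confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
                 roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "homst_report")
}

#' @export
print.homst_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  sensitivity %.4f  specificity %.4f  AUC %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

# Balance a training fold by dropping rotating members of the larger class
# (rotation keyed to the held-out subject's identity rank, so the choice is
# deterministic and order-invariant). Leave-one-out otherwise trains on
# class-imbalanced folds whose majority is always the held-out subject's
# opposite class; the imbalance leaks through the mining support bars and
# the SVM geometry and yields systematically below-chance null accuracy.
balance_fold <- function(train_idx, labels, ids, rot_rank) {
  repeat {
    n1 <- sum(labels[train_idx] == 1L)
    n0 <- sum(labels[train_idx] == 0L)
    if (n1 == n0) return(train_idx)
    big <- if (n1 > n0) 1L else 0L
    cand <- train_idx[labels[train_idx] == big]
    cand <- cand[order(ids[cand])]
    train_idx <- setdiff(train_idx, cand[(rot_rank %% length(cand)) + 1L])
    rot_rank <- rot_rank + 1L
  }
}

# fold assignment keyed to subject identity (not position) so predictions do
# not depend on subject ordering
stratified_folds <- function(labels, k, seed, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    member <- which(labels == cl)[order(ids[labels == cl])]
    fold[member] <- rep_len(seq_len(k), length(member))[
      sample(length(member))]
  }
  fold
}

# Build the per-fold kernel set: WL kernel over pattern-restricted graphs,
# vector kernel over BH-selected features (training statistics). Returns
# normalized full-cohort kernel matrices plus the selection/patterns used.
build_fold_kernels <- function(features, train_idx, protocol) {
  labels <- features$labels
  sel <- select_features(features$fm[train_idx, , drop = FALSE],
                         labels[train_idx], q = protocol$q)
  graphs_tr <- lapply(features$trees[train_idx], tree_to_graph)
  pos_tr <- which(labels[train_idx] == 1L)
  neg_tr <- which(labels[train_idx] == 0L)
  pats_pos <- gspan_mine(graphs_tr[pos_tr], protocol$fq_pos,
                         protocol$max_pattern_edges)
  pats_neg <- gspan_mine(graphs_tr[neg_tr], protocol$fq_neg,
                         protocol$max_pattern_edges)
  scored <- discriminative_scores(pats_pos, pats_neg,
                                  graphs_tr[pos_tr], graphs_tr[neg_tr])
  patterns <- suppressWarnings(
    select_top_k(scored, protocol$k_patterns,
                 n_pos = length(pos_tr), n_neg = length(neg_tr)))
  subject_graphs <- lapply(features$trees, subject_pattern_graph,
                           patterns = patterns)
  Kg <- suppressWarnings(
    normalize_kernel(wl_subtree_kernel(subject_graphs, h = protocol$wl_h)))
  Kv <- NULL
  if (any(sel$mask)) {
    fsel <- features$fm[, sel$mask, drop = FALSE]
    ctr <- colMeans(fsel[train_idx, , drop = FALSE])
    scl <- apply(fsel[train_idx, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    Kv <- normalize_kernel(vector_kernel(fsel, center = ctr, scale = scl))
  }
  list(Kg = Kg, Kv = Kv, selection = sel, patterns = patterns)
}

grid_search <- function(Kg, Kv, labels, train_idx, protocol, ids = NULL) {
  n_inner <- min(protocol$inner_folds, min(table(labels[train_idx])))
  folds <- stratified_folds(labels[train_idx], n_inner, protocol$seed,
                            ids = ids[train_idx])
  a_grid <- if (is.null(Kv)) 0 else protocol$a_grid
  best <- list(acc = -1, a = a_grid[1], cost = protocol$cost_grid[1])
  for (a in a_grid) {
    for (cost in protocol$cost_grid) {
      correct <- 0L; total <- 0L
      for (f in seq_len(n_inner)) {
        tr <- train_idx[folds != f]; te <- train_idx[folds == f]
        if (length(unique(labels[tr])) != 2 || !length(te)) next
        kl <- kernel_pair(Kg, Kv, a)
        model <- try(train_mksvm(lapply(kl$mats, function(K)
          K[tr, tr, drop = FALSE]), labels[tr], kl$w, cost), silent = TRUE)
        if (inherits(model, "try-error")) next
        sc <- predict(model, lapply(kl$mats, function(K)
          K[te, tr, drop = FALSE]))
        correct <- correct + sum((sc > 0) == (labels[te] == 1L))
        total <- total + length(te)
      }
      acc <- if (total) correct / total else -1
      if (acc > best$acc + 1e-12) best <- list(acc = acc, a = a, cost = cost)
    }
  }
  best
}

kernel_pair <- function(Kg, Kv, a) {
  if (is.null(Kv)) list(mats = list(Kg), w = 1)
  else list(mats = list(Kv, Kg), w = c(a, 1 - a))
}

#' Cross-validated multikernel classification of a cohort
#'
#' Outer leave-one-out evaluation. Each outer training fold is first
#' class-balanced by dropping rotating members of the larger class (see the
#' package vignette: unbalanced leave-one-out folds otherwise bias null
#' accuracy below chance). In the default nested protocol every balanced
#' training fold then redoes KS/BH feature selection, per-group gSpan
#' mining, discriminative pattern selection and kernel construction on the
#' training subjects only; an inner stratified CV picks the kernel weight
#' `a` and SVM cost by accuracy (ties toward smaller `a`, then smaller
#' cost). With `whole_sample_selection`, selection, mining and kernels are computed once
#' on the whole sample and only the SVM is cross-validated.
#'
#' @param features A `homst_features` object from [extract_features()].
#' @param protocol An [eval_protocol()].
#' @return A `homst_report` (see [report_metrics()]) with an extra
#'   `fold_choices` data frame of the selected `(a, cost)` per fold.
#' @export
cross_validate <- function(features, protocol = eval_protocol()) {
  labels <- features$labels
  n <- length(labels)
  if (n < 6 || length(unique(labels)) != 2)
    stop("need at least 6 subjects and both classes")
  scores <- numeric(n)
  choices <- data.frame(subject = seq_len(n), a = NA_real_, cost = NA_real_)
  shared <- if (protocol$whole_sample_selection)
    build_fold_kernels(features, seq_len(n), protocol) else NULL
  ids <- features$subject_ids
  for (s in seq_len(n)) {
    train_idx <- balance_fold(setdiff(seq_len(n), s), labels, ids,
                              rot_rank = match(ids[s], sort(ids)) - 1L)
    kset <- if (protocol$whole_sample_selection) shared
    else build_fold_kernels(features, train_idx, protocol)
    best <- grid_search(kset$Kg, kset$Kv, labels, train_idx, protocol,
                        ids = features$subject_ids)
    kl <- kernel_pair(kset$Kg, kset$Kv, best$a)
    model <- train_mksvm(lapply(kl$mats, function(K)
      K[train_idx, train_idx, drop = FALSE]), labels[train_idx], kl$w,
      best$cost)
    scores[s] <- predict(model, lapply(kl$mats, function(K)
      K[s, train_idx, drop = FALSE]))
    choices$a[s] <- best$a; choices$cost[s] <- best$cost
  }
  rep <- report_metrics(labels, scores)
  rep$fold_choices <- choices
  rep$scores <- scores
  rep
}
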