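#' Run the full classification pipeline end to end
#'
#' Generates (or reads) a cohort, builds every subject's high-order network
#' and spanning tree, selects local tree features, mines and scores frequent
#' subgraphs, and evaluates the multikernel SVM by cross-validation. All
#' intermediate artifacts are written under `out_dir` together with a
#' manifest recording the configuration, seed, package version and per-file
#' checksums.
#'
#' @param config List (or path to a YAML file) with optional entries:
#'   `cohort_dir` (read an existing cohort) or `cohort` (arguments for
#'   [cohort_config()]); `window` (list with `N`, `S`); `protocol`
#'   (arguments for [eval_protocol()]); `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `report`, `features`, whole-sample
#'   `selection` and `patterns`, and the manifest path.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("cohort", {
    if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
    else {
      args <- config$cohort
      if (is.null(args)) args <- list()
      if (is.null(args$seed)) args$seed <- seed
      cc <- do.call(cohort_config, args)
      ch <- generate_cohort(cc)
      write_cohort(ch, file.path(out_dir, "cohort"))
      ch
    }
  })
  N <- if (!is.null(config$window$N)) config$window$N
  else min(90L, max(3L, floor(ncol(cohort[[1]]$series) / 4)))
  S <- if (!is.null(config$window$S)) config$window$S else 1L
  features <- stage("network+tree", extract_features(cohort, N = N, S = S))
  tree_dir <- file.path(out_dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  for (i in seq_along(features$trees))
    write_tree(features$trees[[i]],
               file.path(tree_dir, paste0(features$subject_ids[i], ".tsv")))
  utils::write.table(
    data.frame(subject_id = features$subject_ids, features$fm,
               check.names = FALSE),
    file.path(out_dir, "features.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(features$pair_index, file.path(out_dir, "pair_index.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  proto_args <- if (is.null(config$protocol)) list() else config$protocol
  if (is.null(proto_args$seed)) proto_args$seed <- seed
  protocol <- do.call(eval_protocol, proto_args)
  # whole-sample descriptive outputs (selection table, abnormal nodes,
  # pattern report); classification honesty is governed by the protocol
  sel <- stage("select", select_features(features$fm, features$labels,
                                         q = protocol$q))
  utils::write.table(sel$table, file.path(out_dir, "selection.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(abnormal_nodes(sel, pairs = features$pair_index),
                     file.path(out_dir, "abnormal_nodes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  patterns <- stage("mine", {
    graphs <- lapply(features$trees, tree_to_graph)
    pos <- graphs[features$labels == 1L]; neg <- graphs[features$labels == 0L]
    scored <- discriminative_scores(
      gspan_mine(pos, protocol$fq_pos, protocol$max_pattern_edges),
      gspan_mine(neg, protocol$fq_neg, protocol$max_pattern_edges),
      pos, neg)
    suppressWarnings(select_top_k(scored, protocol$k_patterns,
                                  n_pos = length(pos), n_neg = length(neg)))
  })
  write_patterns(patterns, file.path(out_dir, "patterns.tsv"))
  report <- stage("classify", cross_validate(features, protocol))
  jsonlite::write_json(
    list(accuracy = report$accuracy, sensitivity = report$sensitivity,
         specificity = report$specificity, auc = report$auc,
         confusion = as.list(report$confusion)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(report$roc, file.path(out_dir, "roc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    config = config, seed = seed, window = list(N = N, S = S),
    package_version = as.character(utils::packageVersion("homst")),
    r_version = R.version.string,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(report = report, features = features, selection = sel,
                 patterns = patterns,
                 manifest = file.path(out_dir, "manifest.json")))
}

#' Write a pattern report TSV
#'
#' One row per pattern: canonical key, edge count, group frequencies,
#' discriminative score, and the pattern's edges as decoded label pairs.
#'
#' @param patterns A `homst_scored` (or `homst_patterns`) list.
#' @param path Output TSV path.
#' @export
write_patterns <- function(patterns, path) {
  rows <- lapply(seq_along(patterns), function(i) {
    p <- patterns[[i]]
    ek <- paste(edge_label_keys(p$graph), collapse = ";")
    data.frame(pattern = i, n_edges = p$n_edges,
               fq_pos = if (!is.null(p$fq_pos)) p$fq_pos else NA_real_,
               fq_neg = if (!is.null(p$fq_neg)) p$fq_neg else NA_real_,
               score = if (!is.null(p$score)) p$score else NA_real_,
               edges = ek, key = p$key, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(pattern = integer(0), n_edges = integer(0),
                  fq_pos = numeric(0), fq_neg = numeric(0), score = numeric(0),
                  edges = character(0), key = character(0))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
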