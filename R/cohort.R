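#' Configuration for a synthetic two-group cohort
#'
#' Describes a labeled cohort of regional (ROI) time series whose dynamic
#' pairwise coupling differs between two groups. Group 1 subjects carry a
#' slowly oscillating mixing weight of amplitude `effect_size` on each
#' `effect_pairs` coupling (two full cycles over the series, subject-specific
#' phase), group 0 subjects the constant time-average coupling (zero), so the
#' group contrast lives in the *dynamics* of windowed correlation rather than
#' in its static mean.
#'
#' @param n_per_group Subjects per class.
#' @param R Number of ROIs (rows of each series matrix), at least 3.
#' @param M Time points per series, at least 2.
#' @param effect_pairs List of length-2 integer vectors: ROI pairs whose
#'   coupling is group-modulated. Pairs must not share ROIs.
#' @param effect_size Coupling amplitude in \[0, 1\]; the mixing weight of a
#'   modulated pair oscillates in \[-effect_size, effect_size\] for group 1
#'   and is fixed at its time average (zero) for group 0.
#' @param noise_sd Standard deviation of additive Gaussian measurement noise.
#' @param seed Integer RNG seed; identical seeds give bit-identical cohorts.
#' @return An object of class `homst_cohort_config`.
#' @export
cohort_config <- function(n_per_group = 20L, R = 10L, M = 120L,
                          effect_pairs = list(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
                          effect_size = 0.8, noise_sd = 0.2, seed = 1L) {
  stopifnot(is.numeric(n_per_group), length(n_per_group) == 1L, n_per_group >= 1)
  if (!is.numeric(R) || length(R) != 1L || R < 3)
    stop("R must be a single integer >= 3")
  if (!is.numeric(M) || length(M) != 1L || M < 2)
    stop("M must be a single integer >= 2")
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      effect_size < 0 || effect_size > 1)
    stop("effect_size must lie in [0, 1]")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("noise_sd must be a nonnegative number")
  if (!is.list(effect_pairs))
    stop("effect_pairs must be a list of length-2 integer vectors")
  used <- integer(0)
  for (p in effect_pairs) {
    if (length(p) != 2L || any(p < 1) || any(p > R) || p[1] == p[2])
      stop("each effect pair must be two distinct ROI indices in 1..R")
    if (any(p %in% used))
      stop("effect pairs must not share ROIs")
    used <- c(used, p)
  }
  structure(list(n_per_group = as.integer(n_per_group), R = as.integer(R),
                 M = as.integer(M), effect_pairs = effect_pairs,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "homst_cohort_config")
}

new_subject <- function(subject_id, label, series) {
  structure(list(subject_id = subject_id, label = as.integer(label),
                 series = series),
            class = "homst_subject")
}

#' Generate a labeled synthetic cohort of ROI time series
#'
#' Each subject's series is built from independent standard-normal latent
#' signals; for every configured effect pair (i, j), ROI j is the unit-variance
#' mixture `sqrt(1 - lambda(t)^2) * z_j + lambda(t) * z_i`, where the mixing
#' weight `lambda(t) = effect_size * sin(2 pi t / (M/2) + phase)` oscillates
#' sinusoidally (two cycles over the series) for group 1 and stays at the
#' constant time average (zero) for group 0. All effect pairs of a group-1
#' subject share one subject-level modulator phase: their coupling
#' fluctuations are coherent, the kind of structure a
#' correlation-of-correlations network is built to detect. Gaussian noise of
#' `noise_sd` is added to every ROI.
#'
#' @param config A [cohort_config()].
#' @return List of `2 * n_per_group` subjects (class `homst_subject`), group 0
#'   first, each with fields `subject_id`, `label` and the `R x M` matrix
#'   `series`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "homst_cohort_config"))
    config <- do.call(cohort_config, as.list(config))
  set.seed(config$seed)
  t_idx <- seq_len(config$M)
  cohort <- vector("list", 2L * config$n_per_group)
  pos <- 0L
  for (label in c(0L, 1L)) {
    for (s in seq_len(config$n_per_group)) {
      z <- matrix(stats::rnorm(config$R * config$M), nrow = config$R)
      phase <- stats::runif(1, 0, 2 * pi)  # subject-level modulator
      x <- z
      for (p in config$effect_pairs) {
        lambda <- if (label == 1L)
          config$effect_size * sin(2 * pi * t_idx / (config$M / 2) + phase)
        else rep(0, config$M)
        x[p[2], ] <- sqrt(1 - lambda^2) * z[p[2], ] + lambda * z[p[1], ]
      }
      x <- x + config$noise_sd * matrix(stats::rnorm(config$R * config$M),
                                        nrow = config$R)
      pos <- pos + 1L
      cohort[[pos]] <- new_subject(sprintf("sub%03d_g%d", s, label), label, x)
    }
  }
  cohort
}

#' Write a cohort as delimited text matrices plus a label table
#'
#' One `<subject_id>.csv` per subject (no header, one ROI per row) and a
#' `labels.csv` table with columns `subject_id,label`.
#'
#' @param cohort List of `homst_subject` objects.
#' @param dir Output directory (created if missing).
#' @param sep Field separator, comma by default.
#' @export
write_cohort <- function(cohort, dir, sep = ",") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sub in cohort) {
    utils::write.table(format(sub$series, digits = 17, trim = TRUE,
                              scientific = TRUE),
                       file.path(dir, paste0(sub$subject_id, ".csv")),
                       sep = sep, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  labs <- data.frame(subject_id = vapply(cohort, `[[`, "", "subject_id"),
                     label = vapply(cohort, `[[`, 0L, "label"))
  utils::write.table(labs, file.path(dir, "labels.csv"), sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort from a directory of delimited matrices
#'
#' Expects the layout written by [write_cohort()]: per-subject numeric
#' matrices named `<subject_id>.csv` and a `labels.csv` two-column table.
#' All subjects must share dimensions; rows with zero variance are rejected
#' with the subject and row named.
#'
#' @param dir Directory containing the matrices and label table.
#' @param sep Field separator, comma by default.
#' @return List of `homst_subject` objects.
#' @export
read_cohort <- function(dir, sep = ",") {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) stop("label table not found: ", lab_path)
  labs <- utils::read.table(lab_path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(labs)))
    stop("label table must have columns subject_id, label")
  if (!all(labs$label %in% c(0L, 1L)))
    stop("unknown label value; labels must be 0 or 1")
  dims <- NULL
  cohort <- vector("list", nrow(labs))
  for (r in seq_len(nrow(labs))) {
    id <- labs$subject_id[r]
    path <- file.path(dir, paste0(id, ".csv"))
    if (!file.exists(path)) stop("series file not found for subject ", id)
    x <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    storage.mode(x) <- "double"
    dimnames(x) <- NULL
    if (anyNA(x)) stop("missing values in series of subject ", id)
    if (is.null(dims)) dims <- dim(x)
    else if (!identical(dims, dim(x)))
      stop("dimension mismatch: subject ", id, " is ",
           paste(dim(x), collapse = "x"), ", expected ",
           paste(dims, collapse = "x"))
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0))
      stop("constant row in subject ", id, ": row ",
           paste(which(sds == 0), collapse = ", "))
    cohort[[r]] <- new_subject(id, labs$label[r], x)
  }
  cohort
}
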