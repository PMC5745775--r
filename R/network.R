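#' Sliding-window scheme over a time series
#'
#' Splits a length-`M` series into `K = floor((M - N) / S) + 1` overlapping
#' windows of length `N` at step `S`; window k covers columns
#' `[(k-1)*S + 1, (k-1)*S + N]` (1-based, inclusive).
#'
#' @param M Total series length.
#' @param N Window length, `1 <= N <= M`. Default 90.
#' @param S Step between successive windows, `S >= 1`. Default 1.
#' @return Object of class `homst_windows` with fields `M, N, S, K, starts,
#'   ends`.
#' @export
make_windows <- function(M, N = 90L, S = 1L) {
  if (!is.numeric(N) || N < 1 || N > M) stop("window length N must satisfy 1 <= N <= M")
  if (!is.numeric(S) || S < 1) stop("step S must be >= 1")
  K <- floor((M - N) / S) + 1L
  starts <- (seq_len(K) - 1L) * S + 1L
  structure(list(M = as.integer(M), N = as.integer(N), S = as.integer(S),
                 K = as.integer(K), starts = as.integer(starts),
                 ends = as.integer(starts + N - 1L)),
            class = "homst_windows")
}

#' Pearson product-moment correlation of two vectors
#'
#' Strict wrapper over [stats::cor()]: equal lengths of at least 2 and
#' nonzero variance in both inputs are required.
#'
#' @param x,y Numeric vectors.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input to pearson correlation")
  stats::cor(x, y)
}

#' Windowed low-order functional connectivity stack
#'
#' For every sliding window, the ROI-by-ROI Pearson correlation matrix of the
#' windowed series. A ROI that is constant inside any window is an error (a
#' silent NaN would poison every downstream pair-node correlation).
#'
#' @param subject A `homst_subject` or a numeric `R x M` matrix.
#' @param scheme A [make_windows()] scheme with matching `M`.
#' @return `R x R x K` array; each slice is symmetric with unit diagonal.
#' @export
windowed_low_order <- function(subject, scheme) {
  x <- if (inherits(subject, "homst_subject")) subject$series else subject
  id <- if (inherits(subject, "homst_subject")) subject$subject_id else "<matrix>"
  if (!is.matrix(x)) stop("subject series must be a matrix")
  if (ncol(x) != scheme$M)
    stop("series has ", ncol(x), " columns but the window scheme expects ", scheme$M)
  R <- nrow(x)
  out <- array(NA_real_, c(R, R, scheme$K))
  for (k in seq_len(scheme$K)) {
    w <- x[, scheme$starts[k]:scheme$ends[k], drop = FALSE]
    sds <- apply(w, 1, stats::sd)
    if (any(sds == 0))
      stop("constant subseries in window ", k, " for ROI ",
           paste(which(sds == 0), collapse = ", "), " (subject ", id, ")")
    C <- stats::cor(t(w))
    C[C > 1] <- 1; C[C < -1] <- -1
    diag(C) <- 1
    out[, , k] <- C
  }
  out
}

#' ROI-pair / pair-node index
#'
#' Deterministic row-major bijection between unordered ROI pairs (i < j) and
#' pair-node indices q = 1..P, P = R(R-1)/2: (1,2), (1,3), ..., (R-1,R).
#'
#' @param R Number of ROIs.
#' @return Data frame with columns `q, i, j`.
#' @export
pair_index <- function(R) {
  stopifnot(R >= 2)
  i <- rep(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(a) (a + 1L):R))
  data.frame(q = seq_along(i), i = i, j = j)
}

#' Correlation time series of every ROI pair
#'
#' Row q traces pair q's windowed correlation across windows k = 1..K, in
#' [pair_index()] order.
#'
#' @param stack `R x R x K` array from [windowed_low_order()].
#' @return `P x K` matrix with rownames `"i_j"` and attribute `pair_index`.
#' @export
stack_correlation_series <- function(stack) {
  R <- dim(stack)[1]; K <- dim(stack)[3]
  idx <- pair_index(R)
  y <- matrix(NA_real_, nrow(idx), K)
  for (q in seq_len(nrow(idx)))
    y[q, ] <- stack[idx$i[q], idx$j[q], ]
  rownames(y) <- paste0(idx$i, "_", idx$j)
  attr(y, "pair_index") <- idx
  y
}

#' High-order functional connectivity network
#'
#' Pearson correlation between every pair of ROI-pair correlation time
#' series: entry (q, r) correlates pair-node q's windowed-correlation series
#' with pair-node r's, reflecting interactions among up to four ROIs.
#'
#' @param series `P x K` matrix from [stack_correlation_series()]; needs
#'   `K >= 3` and no constant row.
#' @return `P x P` symmetric matrix with unit diagonal, rownames as `series`.
#' @export
high_order <- function(series) {
  if (ncol(series) < 3)
    stop("high-order correlation needs at least 3 windows (K >= 3); got K = ",
         ncol(series))
  sds <- apply(series, 1, stats::sd)
  if (any(sds == 0))
    stop("constant correlation series for ROI pair ",
         paste(rownames(series)[sds == 0], collapse = ", "))
  H <- stats::cor(t(series))
  H[H > 1] <- 1; H[H < -1] <- -1
  diag(H) <- 1
  H <- (H + t(H)) / 2
  attr(H, "pair_index") <- attr(series, "pair_index")
  H
}

#' Write a high-order network as an edge-list TSV
#'
#' One row per unordered pair-node pair: `node_q, node_r, weight`. The
#' symmetric-matrix CSV form is just `write.table(H, ...)`.
#'
#' @param H Symmetric matrix from [high_order()].
#' @param path Output TSV path.
#' @export
write_network_edgelist <- function(H, path) {
  labs <- if (!is.null(rownames(H))) rownames(H) else as.character(seq_len(nrow(H)))
  ut <- which(upper.tri(H), arr.ind = TRUE)
  utils::write.table(
    data.frame(node_q = labs[ut[, 1]], node_r = labs[ut[, 2]],
               weight = H[ut]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build one subject's high-order network in a single call
#'
#' Convenience chain: windows, low-order stack, pair-correlation series,
#' high-order matrix.
#'
#' @inheritParams windowed_low_order
#' @param N,S Window length and step for [make_windows()].
#' @return `P x P` high-order matrix (see [high_order()]).
#' @export
high_order_network <- function(subject, N = 90L, S = 1L) {
  x <- if (inherits(subject, "homst_subject")) subject$series else subject
  scheme <- make_windows(ncol(x), N, S)
  high_order(stack_correlation_series(windowed_low_order(subject, scheme)))
}
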