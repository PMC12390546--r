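#' Reduce each window-channel to one summary observation
#'
#' The ANOVA ranking treats one window as one observation per channel; this
#' reducer collapses the time axis. The default is the time-mean of the
#' standardized signal; median and AUC (mean absolute value) are available.
#'
#' @param ws A `fnirs_windows` object.
#' @param reducer `"mean"`, `"median"` or `"auc"`.
#' @return Numeric matrix, n_windows x n_channels.
#' @export
channel_summary <- function(ws, reducer = c("mean", "median", "auc")) {
  stopifnot(inherits(ws, "fnirs_windows"))
  reducer <- match.arg(reducer)
  d <- dim(ws$windows)
  if (d[1] < 1) abort("empty window set.")
  f <- switch(reducer,
    mean = function(m) rowMeans(m),
    median = function(m) apply(m, 1, stats::median),
    auc = function(m) rowMeans(abs(m))
  )
  out <- matrix(0, d[1], d[2])
  for (j in seq_len(d[2])) out[, j] <- f(matrix(ws$windows[, j, ], d[1], d[3]))
  colnames(out) <- ws$channels$name
  out
}

#' One-way ANOVA F score per channel
#'
#' For each channel (column of the summary matrix) computes the one-way
#' between-groups F statistic F = \[SSB / (g - 1)\] / \[SSW / (N - g)\]
#' against the window class labels, with the upper-tail p-value from the
#' F(g - 1, N - g) distribution. Channels with zero within-group variance but
#' distinct group means get `F = Inf` (perfect separation, ranked first);
#' zero within- and between-group variance gives `F = 0`. Ranks are dense by
#' descending F with ties broken by ascending channel index.
#'
#' @param summary Numeric matrix, observations x channels (see
#'   [channel_summary()]).
#' @param labels Class label per row; at least two classes, each with at
#'   least two observations.
#' @return A tibble of class `feature_scores`: channel, f_stat, p_value, rank.
#' @export
anova_f_scores <- function(summary, labels) {
  labels <- droplevels(as.factor(labels))
  g <- nlevels(labels)
  N <- nrow(summary)
  if (length(labels) != N) abort("one label per summary row is required.")
  if (g < 2) abort("ANOVA needs at least two classes.")
  cnt <- table(labels)
  if (any(cnt < 2)) {
    abort(sprintf(
      "every class needs >= 2 observations (got: %s).",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", ")
    ))
  }
  grand <- colMeans(summary)
  ssb <- numeric(ncol(summary))
  ssw <- numeric(ncol(summary))
  for (lev in levels(labels)) {
    rows <- labels == lev
    m <- colMeans(summary[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (m - grand)^2
    ssw <- ssw + colSums((summary[rows, , drop = FALSE] -
      matrix(m, sum(rows), ncol(summary), byrow = TRUE))^2)
  }
  msb <- ssb / (g - 1)
  msw <- ssw / (N - g)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  p <- ifelse(is.finite(f), pf(f, g - 1, N - g, lower.tail = FALSE), 0)
  ord <- order(-f, seq_along(f)) # descending F, ties by ascending index
  rank <- integer(length(f))
  rank[ord] <- seq_along(f)
  tibble::new_tibble(
    tibble::tibble(
      channel = seq_len(ncol(summary)),
      name = colnames(summary) %||% as.character(seq_len(ncol(summary))),
      f_stat = f, p_value = p, rank = rank
    ),
    class = "feature_scores"
  )
}

#' Retain the top-K channels by F score
#'
#' @param scores A `feature_scores` tibble from [anova_f_scores()].
#' @param k Number of channels to keep (the study default is 50). If `k`
#'   exceeds the number of channels, all channels are returned with a
#'   warning.
#' @return A list of class `selected_set`: `indices` (channel indices in
#'   descending-F order), `k`, and the `scores` snapshot.
#' @export
select_top_k <- function(scores, k = 50) {
  stopifnot(inherits(scores, "feature_scores"))
  check_scalar(k, "k", positive = TRUE)
  n <- nrow(scores)
  if (k > n) {
    warn(sprintf("k = %d exceeds the %d available channels; keeping all.", k, n))
    k <- n
  }
  idx <- scores$channel[order(scores$rank)][seq_len(k)]
  structure(list(indices = idx, k = as.integer(k), scores = scores),
    class = "selected_set"
  )
}

#' @export
print.selected_set <- function(x, ...) {
  cat(sprintf("<selected_set: top %d of %d channels by ANOVA F>\n", x$k, nrow(x$scores)))
  print(head(dplyr::arrange(x$scores, .data$rank), 5))
  invisible(x)
}

#' Pearson correlation matrix of selected features
#'
#' Diagnostic correlation structure of the retained channels (the study
#' reports this as a heatmap; no channel is dropped by correlation). A
#' zero-variance column yields NaN entries with a warning rather than a
#' silent zero.
#'
#' @param summary Observations x channels matrix, typically already
#'   restricted to a [select_top_k()] selection
#'   (`summary[, selected$indices]`).
#' @return Symmetric k x k correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(summary) {
  if (nrow(summary) < 2) abort("need >= 2 observations for correlations.")
  sds <- apply(summary, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf(
      "%d zero-variance column(s); their correlations are NaN.",
      sum(sds == 0)
    ))
  }
  suppressWarnings(cor(summary))
}
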