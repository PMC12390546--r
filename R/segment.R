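#' Segment recordings into labelled fixed-length windows
#'
#' Extracts pure-label windows from maximal runs of a single task condition
#' (rest samples never enter a window; windows straddling block boundaries
#' are discarded). In `"nonoverlap"` mode windows tile each run with stride
#' equal to the window length; in `"overlap"` mode a sliding window advances
#' by `step_seconds` (default half the window, the most common convention),
#' so neighbouring windows share `n - step` samples. A run of length L yields
#' `floor((L - n) / stride) + 1` windows when `L >= n`, else none.
#'
#' @param x A `fnirs_recording` or a list of recordings (their windows are
#'   concatenated, with provenance kept per window).
#' @param window_seconds Window length in seconds.
#' @param mode `"overlap"` or `"nonoverlap"`.
#' @param step_seconds Sliding step in seconds for overlap mode; defaults to
#'   `window_seconds / 2`. Must convert to fewer samples than the window.
#' @return An object of class `fnirs_windows`: list with `windows` (array
#'   n_windows x channels x n_samples), `labels` (factor over the three task
#'   conditions), `meta` (tibble: recording, start, mode), `window_seconds`,
#'   `fs`, `channels` (channel metadata of the source).
#' @examples
#' cfg <- sim_config(n_subjects = 1, n_sites = 4)
#' ws <- segment_windows(simulate_session(cfg, 1), 10, "nonoverlap")
#' ws
#' @export
segment_windows <- function(x, window_seconds,
                            mode = c("nonoverlap", "overlap"),
                            step_seconds = window_seconds / 2) {
  mode <- match.arg(mode)
  if (inherits(x, "fnirs_recording")) x <- list(x)
  stopifnot(length(x) > 0, all(vapply(x, inherits, logical(1), "fnirs_recording")))
  fs <- x[[1]]$fs
  n <- seconds_to_samples(window_seconds, fs)
  stride <- if (mode == "nonoverlap") {
    n
  } else {
    s <- seconds_to_samples(step_seconds, fs)
    if (s >= n) abort("overlap mode requires step_seconds to convert to fewer samples than the window.")
    s
  }

  pieces <- lapply(x, function(rec) {
    if (rec$fs != fs) abort("all recordings must share one sampling rate.")
    runs <- task_runs(rec$condition_track)
    starts <- integer(0)
    labels <- character(0)
    for (i in seq_len(nrow(runs))) {
      L <- runs$end[i] - runs$start[i] + 1L
      if (L < n) next
      k <- (L - n) %/% stride + 1L
      st <- runs$start[i] + stride * (seq_len(k) - 1L)
      starts <- c(starts, st)
      labels <- c(labels, rep(runs$label[i], k))
    }
    if (!length(starts)) {
      return(NULL)
    }
    w <- array(0, c(length(starts), nrow(rec$data), n))
    for (i in seq_along(starts)) {
      w[i, , ] <- rec$data[, starts[i]:(starts[i] + n - 1L)]
    }
    list(
      w = w, labels = labels,
      meta = tibble::tibble(
        recording = rec$subject_id, start = starts, mode = mode
      ),
      channels = rec$channels
    )
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    abort("no task run is long enough to contain a single window.")
  }
  windows <- do.call(abind_windows, lapply(pieces, `[[`, "w"))
  structure(
    list(
      windows = windows,
      labels = factor(unlist(lapply(pieces, `[[`, "labels")), levels = TASK_LEVELS),
      meta = dplyr::bind_rows(lapply(pieces, `[[`, "meta")),
      window_seconds = window_seconds, fs = fs,
      channels = pieces[[1]]$channels
    ),
    class = "fnirs_windows"
  )
}

## maximal runs of a constant non-rest condition
task_runs <- function(track) {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "rest"
  tibble::tibble(
    label = r$values[keep], start = starts[keep], end = ends[keep]
  )
}

## rbind 3-d window arrays along the first axis
abind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1) {
    return(parts[[1]])
  }
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0, c(total, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    out[at + seq_len(k), , ] <- p
    at <- at + k
  }
  out
}

#' Subset a window set
#'
#' @param ws A `fnirs_windows` object.
#' @param i Window indices (first axis).
#' @param channels Optional channel indices (second axis).
#' @return A `fnirs_windows` with the selected windows/channels.
#' @export
subset_windows <- function(ws, i = seq_len(dim(ws$windows)[1]), channels = NULL) {
  stopifnot(inherits(ws, "fnirs_windows"))
  ws$windows <- ws$windows[i, , , drop = FALSE]
  ws$labels <- ws$labels[i]
  ws$meta <- ws$meta[i, ]
  if (!is.null(channels)) {
    ws$windows <- ws$windows[, channels, , drop = FALSE]
    ws$channels <- ws$channels[channels, ]
  }
  ws
}

#' @export
print.fnirs_windows <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf(
    "<fnirs_windows: %d windows x %d channels x %d samples (%g s, %s)>\n",
    d[1], d[2], d[3], x$window_seconds, paste(unique(x$meta$mode), collapse = "/")
  ))
  print(table(x$labels))
  invisible(x)
}
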