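## Plain-text interchange: wide CSV for numeric arrays (full double precision,
## "%.17g", so write-then-read is bit-exact) plus a JSON sidecar for metadata.

write_matrix_csv <- function(m, path) {
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, path)
}

read_matrix_csv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), length(rows), byrow = TRUE)
}

#' Write a recording to disk (CSV + JSON sidecar)
#'
#' Writes `<id>_data.csv` (channels x samples, full precision) and
#' `<id>_meta.json` (channel table, sampling rate, condition track,
#' subject id). The round trip through [read_recording()] is bit-exact.
#'
#' @param rec A `fnirs_recording`.
#' @param dir Output directory (created if needed).
#' @return The data-file path, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "fnirs_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, rec$subject_id)
  write_matrix_csv(rec$data, paste0(base, "_data.csv"))
  jsonlite::write_json(
    list(
      subject_id = rec$subject_id, fs = rec$fs,
      condition_track = rec$condition_track,
      channels = rec$channels
    ),
    paste0(base, "_meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(base, "_data.csv"))
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory holding the pair of files.
#' @param subject_id Base name used when writing.
#' @return A `fnirs_recording`.
#' @export
read_recording <- function(dir, subject_id) {
  base <- file.path(dir, subject_id)
  meta_path <- paste0(base, "_meta.json")
  data_path <- paste0(base, "_data.csv")
  if (!file.exists(meta_path) || !file.exists(data_path)) {
    abort(sprintf("no recording `%s` under %s.", subject_id, dir))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  data <- read_matrix_csv(data_path)
  if (nrow(data) == 0 || nrow(meta$channels) == 0) {
    abort(sprintf("recording `%s` has no channels.", subject_id))
  }
  new_recording(
    data, tibble::as_tibble(meta$channels), meta$fs,
    meta$condition_track, meta$subject_id
  )
}

#' Write a window set to disk (CSV + JSON manifest)
#'
#' The window tensor is stored as a 2-D CSV (first two axes collapsed,
#' column-major) with its dimensions, labels and per-window provenance in
#' `<name>_manifest.json`; [read_windows()] reconstructs the array
#' bit-exactly.
#'
#' @param ws A `fnirs_windows`.
#' @param dir Output directory.
#' @param name Base file name.
#' @return The manifest path, invisibly.
#' @export
write_windows <- function(ws, dir, name = "windows") {
  stopifnot(inherits(ws, "fnirs_windows"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(ws$windows)
  write_matrix_csv(
    matrix(ws$windows, d[1] * d[2], d[3]),
    file.path(dir, paste0(name, "_data.csv"))
  )
  manifest <- list(
    dim = d, labels = as.character(ws$labels), meta = ws$meta,
    window_seconds = ws$window_seconds, fs = ws$fs, channels = ws$channels
  )
  path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a window set written by [write_windows()]
#'
#' @param dir Directory holding the files.
#' @param name Base file name used when writing.
#' @return A `fnirs_windows`.
#' @export
read_windows <- function(dir, name = "windows") {
  manifest <- jsonlite::read_json(
    file.path(dir, paste0(name, "_manifest.json")),
    simplifyVector = TRUE
  )
  m <- read_matrix_csv(file.path(dir, paste0(name, "_data.csv")))
  d <- manifest$dim
  structure(
    list(
      windows = array(m, d),
      labels = factor(manifest$labels, levels = TASK_LEVELS),
      meta = tibble::as_tibble(manifest$meta),
      window_seconds = manifest$window_seconds, fs = manifest$fs,
      channels = tibble::as_tibble(manifest$channels)
    ),
    class = "fnirs_windows"
  )
}

#' Write feature scores and a selection to CSV
#'
#' One row per channel: site/chromophore metadata (when available), F, p,
#' rank and whether the channel is in the selected set.
#'
#' @param selection A `selected_set` from [select_top_k()].
#' @param path Output CSV path.
#' @param channels Optional channel metadata tibble to join on channel index.
#' @return The written tibble, invisibly.
#' @export
write_selection_csv <- function(selection, path, channels = NULL) {
  stopifnot(inherits(selection, "selected_set"))
  out <- tibble::as_tibble(selection$scores)
  out$selected <- out$channel %in% selection$indices
  if (!is.null(channels)) {
    out <- dplyr::left_join(out, channels, by = "channel")
  }
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write a CV report: per-fold CSV, aggregate CSV and a Markdown table
#'
#' @param report A `cv_report`.
#' @param dir Output directory.
#' @return Paths of the three files, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cv_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  folds_path <- file.path(dir, "report_folds.csv")
  agg_path <- file.path(dir, "report_aggregate.csv")
  md_path <- file.path(dir, "report.md")
  write.csv(tibble::as_tibble(report), folds_path, row.names = FALSE)
  write.csv(glance(report), agg_path, row.names = FALSE)
  writeLines(report_markdown(report), md_path)
  invisible(c(folds = folds_path, aggregate = agg_path, markdown = md_path))
}

#' Format a CV report as a Markdown table
#'
#' One row per grid cell with "mean ± sd" entries at four decimals.
#'
#' @param report A `cv_report`.
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  s <- summary(report)
  header <- paste("|", paste(names(s), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(s)), collapse = " | "), "|")
  body <- apply(s, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, body)
}
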