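#' Save an EEGNet checkpoint
#'
#' Serializes the configuration and all weight tensors into a single JSON
#' archive; [load_eegnet()] restores a model whose weights and predictions
#' agree with the original to double precision (~15 significant digits, the
#' JSON text representation).
#'
#' @param model An `eegnet`.
#' @param path Output file (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_eegnet <- function(model, path) {
  stopifnot(inherits(model, "eegnet"))
  payload <- list(
    format = "fnirsload-eegnet-checkpoint",
    version = 1L,
    config = unclass(model$config),
    params = lapply(model$params, function(p) {
      list(dim = dim(p) %||% length(p), data = as.vector(p))
    }),
    loss_trace = model$loss_trace,
    status = model$status
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an EEGNet checkpoint written by [save_eegnet()]
#'
#' @param path Checkpoint file.
#' @return An `eegnet` model.
#' @export
load_eegnet <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "fnirsload-eegnet-checkpoint")) {
    abort(sprintf("%s is not an EEGNet checkpoint.", path))
  }
  cfg <- payload$config
  int_fields <- c(
    "n_channels", "n_samples", "n_classes", "F1", "D", "F2",
    "kernel1", "kernel2", "t1", "t2"
  )
  cfg[int_fields] <- lapply(cfg[int_fields], as.integer)
  class(cfg) <- "eegnet_config"
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) > 1) array(p$data, p$dim) else p$data
  })
  model <- structure(list(config = cfg, params = params), class = "eegnet")
  model$loss_trace <- payload$loss_trace
  model$status <- payload$status
  model
}

#' Convert a recording to a long tibble
#'
#' One row per (time, channel): sample time in seconds, channel metadata,
#' concentration value and the condition label — the natural shape for
#' dplyr/ggplot2 work and for long-format CSV export.
#'
#' @param rec A `fnirs_recording`.
#' @param channels Channel indices to include (default all).
#' @return A tibble with columns `time`, `channel`, `site`, `chromophore`,
#'   `value`, `condition`, `subject_id`.
#' @export
recording_to_tibble <- function(rec, channels = seq_len(nrow(rec$data))) {
  stopifnot(inherits(rec, "fnirs_recording"))
  n <- ncol(rec$data)
  t_sec <- (seq_len(n) - 1) / rec$fs
  purrr::map_dfr(channels, function(j) {
    tibble::tibble(
      time = t_sec,
      channel = rec$channels$name[j],
      site = rec$channels$site[j],
      chromophore = rec$channels$chromophore[j],
      value = rec$data[j, ],
      condition = rec$condition_track,
      subject_id = rec$subject_id
    )
  })
}
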