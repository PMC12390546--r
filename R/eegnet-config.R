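## Window-length-scaled hyperparameter grid: the published configuration for
## 10 / 20 / 30 s windows at 8.138 Hz. Other window lengths take the nearest
## row.
DYNAMIC_GRID <- data.frame(
  window = c(10, 20, 30),
  F1 = c(8L, 16L, 32L),
  kernel1 = c(32L, 64L, 128L),
  kernel2 = c(8L, 16L, 32L)
)

#' EEGNet configuration with window-length-scaled hyperparameters
#'
#' Builds the full architecture configuration for a given window length. The
#' temporal kernel (`kernel1`), separable depthwise kernel (`kernel2`) and
#' filter counts F1/F2 double with each step of the 10/20/30 s grid
#' (10 s: F1 = 8, kernel1 = 32, kernel2 = 8; 20 s: 16/64/16;
#' 30 s: 32/128/32); the depth multiplier D is 2 throughout, so
#' F2 = F1 x D always holds. Window lengths off the grid use the nearest
#' grid row. The layer table's fixed separable kernel of 16 is available via
#' `kernel2_fixed = TRUE` (it coincides with the 20 s grid value); the
#' default follows the window-adaptive scaling.
#'
#' @param window_seconds Window length in seconds.
#' @param fs Sampling rate in Hz; with `n_samples = NULL` the input length is
#'   `seconds_to_samples(window_seconds, fs)`.
#' @param n_channels Input channel count (after feature selection; default 50).
#' @param n_classes Number of output classes (3 n-back levels).
#' @param dropout Dropout probability (default 0.25).
#' @param pooling `"mean"` (default, the fixed-parameter choice) or `"max"`.
#' @param kernel2_fixed Use the fixed separable kernel length 16 instead of
#'   the window-scaled value.
#' @param n_samples Override the input length in samples.
#' @return A list of class `eegnet_config`.
#' @examples
#' eegnet_config(30)$F2 # 64
#' @export
eegnet_config <- function(window_seconds, fs = 8.138, n_channels = 50,
                          n_classes = 3, dropout = 0.25,
                          pooling = c("mean", "max"),
                          kernel2_fixed = FALSE, n_samples = NULL) {
  pooling <- match.arg(pooling)
  check_scalar(window_seconds, "window_seconds", positive = TRUE)
  row <- DYNAMIC_GRID[which.min(abs(DYNAMIC_GRID$window - window_seconds)), ]
  if (is.null(n_samples)) n_samples <- seconds_to_samples(window_seconds, fs)
  n_samples <- as.integer(n_samples)
  if (n_samples < 32) {
    abort("n_samples must be >= 32: the two pooling stages (4 then 8) must leave >= 1 time step.")
  }
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  D <- 2L
  cfg <- list(
    window_seconds = window_seconds, fs = fs,
    n_channels = as.integer(n_channels), n_samples = n_samples,
    n_classes = as.integer(n_classes),
    F1 = row$F1, D = D, F2 = row$F1 * D,
    kernel1 = row$kernel1,
    kernel2 = if (kernel2_fixed) 16L else row$kernel2,
    dropout = dropout, pooling = pooling,
    activation = "elu", max_norm = 1,
    t1 = n_samples %/% 4L,
    t2 = (n_samples %/% 4L) %/% 8L # final conv length, auto from data shape
  )
  structure(cfg, class = "eegnet_config")
}

#' @export
print.eegnet_config <- function(x, ...) {
  cat(sprintf(
    "<eegnet_config: %g s (%d samples) x %d channels -> %d classes | F1=%d D=%d F2=%d k1=%d k2=%d dropout=%.2f %s-pool>\n",
    x$window_seconds, x$n_samples, x$n_channels, x$n_classes,
    x$F1, x$D, x$F2, x$kernel1, x$kernel2, x$dropout, x$pooling
  ))
  invisible(x)
}

#' Layer table and parameter counts for an EEGNet configuration
#'
#' Symbolic layer-by-layer summary: operation, output shape (for a batch of
#' size B) and trainable parameter count. The time axis shrinks by integer
#' division 4 then 8 across the two pooling stages; the classifier kernel
#' spans the remaining `t2` steps exactly.
#'
#' @param config An [eegnet_config()].
#' @return A tibble with columns `layer`, `output_shape`, `n_params`, plus a
#'   `total_params` attribute.
#' @export
eegnet_shapes <- function(config) {
  stopifnot(inherits(config, "eegnet_config"))
  C <- config$n_channels
  T0 <- config$n_samples
  F1 <- config$F1
  M <- config$F1 * config$D
  F2 <- config$F2
  t1 <- config$t1
  t2 <- config$t2
  N <- config$n_classes
  sh <- function(...) paste0("[B, ", paste(c(...), collapse = ", "), "]")
  layers <- tibble::tribble(
    ~layer, ~output_shape, ~n_params,
    "conv_temporal", sh(F1, C, T0), F1 * config$kernel1,
    "batchnorm_1", sh(F1, C, T0), 2 * F1,
    "conv_spatial_depthwise (max-norm 1)", sh(M, 1, T0), M * C,
    "batchnorm_2", sh(M, 1, T0), 2 * M,
    "elu_1", sh(M, 1, T0), 0,
    "pool_1 (1x4)", sh(M, 1, t1), 0,
    "dropout_1", sh(M, 1, t1), 0,
    "conv_separable_depthwise", sh(M, 1, t1), M * config$kernel2,
    "conv_separable_pointwise", sh(F2, 1, t1), F2 * M,
    "batchnorm_3", sh(F2, 1, t1), 2 * F2,
    "elu_2", sh(F2, 1, t1), 0,
    "pool_2 (1x8)", sh(F2, 1, t2), 0,
    "dropout_2", sh(F2, 1, t2), 0,
    "conv_classifier", sh(N, 1, 1), N * F2 * t2 + N,
    "log_softmax", sh(N, 1, 1), 0,
    "squeeze", sh(N), 0
  )
  attr(layers, "total_params") <- sum(layers$n_params)
  layers
}
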