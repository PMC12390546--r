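#' Fit a per-channel standard scaler
#'
#' Computes the per-channel mean and standard deviation over all samples of
#' the supplied data, for the standardization x' = (x - mu) / sigma applied by
#' [apply_scaler()]. The denominator is the population convention (divide by
#' n), matching the usual standard-scaler definition. Accepts a single
#' recording, a list of recordings (statistics over the concatenated
#' samples), or a `fnirs_windows` set (statistics over all windows and
#' samples). To avoid information leaking across cross-validation folds, fit
#' on training data only; [run_experiment()] does this per fold unless
#' `paper_mode` asks for one global fit.
#'
#' @param x A `fnirs_recording`, list of recordings, or `fnirs_windows`.
#' @param eps If `NULL` (default) a zero-variance channel is an error naming
#'   the channel; otherwise sigma is floored at `eps` with a warning.
#' @return An object of class `channel_scaler`: tibble-backed list with `mu`,
#'   `sigma` (one per channel) and `fitted_on`.
#' @examples
#' cfg <- sim_config(n_subjects = 1, n_sites = 4, block_seconds = 20)
#' rec <- simulate_session(cfg, 1)
#' sc <- fit_scaler(rec)
#' z <- apply_scaler(sc, rec)
#' rowMeans(z$data) # ~0 per channel
#' @export
fit_scaler <- function(x, eps = NULL) {
  mat <- scaler_data_matrix(x) # channels x samples
  n <- ncol(mat)
  if (n < 2) abort("need at least 2 samples per channel to fit a scaler.")
  mu <- rowMeans(mat)
  sigma <- sqrt(rowMeans((mat - mu)^2)) # population (n) denominator
  bad <- which(sigma == 0 | !is.finite(sigma))
  if (length(bad)) {
    if (is.null(eps)) {
      abort(sprintf(
        "zero-variance channel(s): %s; standardization is undefined (set `eps` to guard).",
        paste(bad, collapse = ", ")
      ))
    }
    warn(sprintf("flooring sigma at %g for %d zero-variance channel(s).", eps, length(bad)))
    sigma[bad] <- eps
  }
  structure(
    list(mu = mu, sigma = sigma, fitted_on = scaler_id(x)),
    class = "channel_scaler"
  )
}

#' Apply (or invert) a per-channel standard scaler
#'
#' Applies x' = (x - mu) / sigma channel-wise. With `inverse = TRUE` applies
#' x = x' * sigma + mu, recovering the original scale.
#'
#' @param scaler A `channel_scaler` from [fit_scaler()].
#' @param x A `fnirs_recording` or `fnirs_windows` with the same channel count
#'   the scaler was fitted on.
#' @param inverse Apply the inverse transform instead.
#' @return An object of the same class as `x`.
#' @export
apply_scaler <- function(scaler, x, inverse = FALSE) {
  stopifnot(inherits(scaler, "channel_scaler"))
  n_ch <- length(scaler$mu)
  if (inherits(x, "fnirs_recording")) {
    if (nrow(x$data) != n_ch) abort("channel count does not match the fitted scaler.")
    x$data <- scale_mat(x$data, scaler, inverse)
    x
  } else if (inherits(x, "fnirs_windows")) {
    if (dim(x$windows)[2] != n_ch) abort("channel count does not match the fitted scaler.")
    d <- dim(x$windows)
    # per-channel affine along axis 2, tiled across windows and samples
    mu <- array(rep(scaler$mu, each = d[1]), d)
    sg <- array(rep(scaler$sigma, each = d[1]), d)
    x$windows <- if (inverse) x$windows * sg + mu else (x$windows - mu) / sg
    x
  } else {
    abort("`x` must be a fnirs_recording or fnirs_windows object.")
  }
}

#' @export
print.channel_scaler <- function(x, ...) {
  cat(sprintf(
    "<channel_scaler: %d channels, fitted on %s>\n",
    length(x$mu), x$fitted_on
  ))
  invisible(x)
}

scale_mat <- function(m, scaler, inverse) {
  if (inverse) m * scaler$sigma + scaler$mu else (m - scaler$mu) / scaler$sigma
}

scaler_data_matrix <- function(x) {
  if (inherits(x, "fnirs_recording")) {
    return(x$data)
  }
  if (inherits(x, "fnirs_windows")) {
    d <- dim(x$windows) # windows x channels x samples
    return(matrix(aperm(x$windows, c(2, 1, 3)), d[2], d[1] * d[3]))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "fnirs_recording"))) {
    return(do.call(cbind, lapply(x, function(r) r$data)))
  }
  abort("cannot fit a scaler on this object.")
}

scaler_id <- function(x) {
  if (inherits(x, "fnirs_recording")) {
    return(x$subject_id)
  }
  if (inherits(x, "fnirs_windows")) {
    return(sprintf("%d windows", dim(x$windows)[1]))
  }
  sprintf("%d recordings", length(x))
}
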