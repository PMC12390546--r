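#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical double-gamma HRF used by the session simulator: a
#' positive gamma lobe peaking at `peak_delay` seconds minus an undershoot
#' gamma lobe peaking at `undershoot_delay` seconds, scaled by
#' `undershoot_ratio`. Both lobes use unit-scale gamma densities, so the modes
#' sit at `shape - 1` seconds and the defaults (6 s peak, 16 s undershoot,
#' ratio 1/6) place the sampled argmax in the physiological 5--8 s window.
#' The returned kernel is normalized to unit peak.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Kernel support in seconds; must be at least 20 s so the
#'   peak and undershoot are contained.
#' @param peak_delay Mode of the positive lobe, seconds.
#' @param undershoot_delay Mode of the undershoot lobe, seconds.
#' @param undershoot_ratio Relative amplitude of the undershoot lobe.
#' @return Numeric vector of `seconds_to_samples(duration, fs)` values with
#'   `max(kernel) == 1`; the sample times are `(seq_along(kernel) - 1) / fs`.
#' @examples
#' h <- double_gamma_hrf(8.138, 30)
#' (which.max(h) - 1) / 8.138 # about 6 s
#' @export
double_gamma_hrf <- function(fs, duration,
                             peak_delay = 6,
                             undershoot_delay = 16,
                             undershoot_ratio = 1 / 6) {
  check_scalar(fs, "fs", positive = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  if (duration < 20) {
    abort("`duration` must be >= 20 s so the kernel contains its peak and undershoot.")
  }
  check_scalar(peak_delay, "peak_delay", positive = TRUE)
  check_scalar(undershoot_delay, "undershoot_delay", positive = TRUE)
  n <- seconds_to_samples(duration, fs)
  t <- (seq_len(n) - 1) / fs
  h <- hrf_closed_form(t, peak_delay, undershoot_delay, undershoot_ratio)
  h / max(h)
}

## closed-form double-gamma density (unnormalized); unit-scale gammas so the
## lobe modes are shape - 1 = peak_delay and undershoot_delay
hrf_closed_form <- function(t, peak_delay = 6, undershoot_delay = 16,
                            undershoot_ratio = 1 / 6) {
  dgamma(t, shape = peak_delay + 1, scale = 1) -
    undershoot_ratio * dgamma(t, shape = undershoot_delay + 1, scale = 1)
}
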