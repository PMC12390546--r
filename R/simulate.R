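#' Configuration for the synthetic n-back fNIRS session generator
#'
#' Defines the block design, activation model and noise model used by
#' [simulate_session()]. Defaults emulate a prefrontal high-density recording
#' (102 measurement sites x 2 chromophores = 204 feature channels at
#' 8.138 Hz) during an auditory n-back paradigm with load-graded HbO2
#' activation (2-back > 1-back > 0-back) and standard physiological noise
#' components (cardiac ~1.1 Hz, respiration ~0.25 Hz, Mayer wave ~0.1 Hz,
#' slow drift, white noise).
#'
#' @param n_subjects Number of subjects in the default dataset.
#' @param n_sites Number of measurement sites; each contributes an HbO2 and an
#'   HbR channel, so the recording has `2 * n_sites` feature channels.
#' @param fs Sampling rate in Hz.
#' @param block_seconds Duration of each task block, seconds.
#' @param rest_seconds Rest before the first block and between blocks, seconds.
#' @param blocks_per_condition Number of blocks per n-back level.
#' @param condition_order `"shuffled"` (block order randomized per subject from
#'   the seed) or `"fixed"` (cycling 0-back, 1-back, 2-back).
#' @param amplitude_by_condition Named HbO2 peak concentration change per
#'   condition, micromolar; monotone increasing with load by default.
#' @param hbr_ratio Scale of the inverted HbR response relative to HbO2,
#'   in (0, 1].
#' @param informative_fraction Fraction of sites carrying task activation,
#'   in (0, 1].
#' @param noise List of noise components; see [noise_config()].
#' @param subject_gain_sd Between-subject SD of the multiplicative response
#'   gain (gain ~ 1 + N(0, sd), floored at 0.2).
#' @param hrf_peak,hrf_undershoot,hrf_ratio Double-gamma HRF parameters passed
#'   to [double_gamma_hrf()].
#' @param seed Root RNG seed; per-subject streams are derived with
#'   [derive_seed()] so adding subjects never perturbs earlier ones.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 2, n_sites = 8, block_seconds = 20)
#' rec <- simulate_session(cfg, subject = 1)
#' rec
#' @export
sim_config <- function(n_subjects = 8,
                       n_sites = 102,
                       fs = 8.138,
                       block_seconds = 30,
                       rest_seconds = 15,
                       blocks_per_condition = 4,
                       condition_order = c("shuffled", "fixed"),
                       amplitude_by_condition = c(
                         "0-back" = 0.2, "1-back" = 0.5, "2-back" = 1.0
                       ),
                       hbr_ratio = 0.4,
                       informative_fraction = 0.3,
                       noise = noise_config(),
                       subject_gain_sd = 0.25,
                       hrf_peak = 6, hrf_undershoot = 16, hrf_ratio = 1 / 6,
                       seed = 1) {
  condition_order <- match.arg(condition_order)
  check_scalar(fs, "fs", positive = TRUE)
  check_scalar(block_seconds, "block_seconds", positive = TRUE)
  check_scalar(rest_seconds, "rest_seconds", positive = TRUE)
  check_scalar(n_sites, "n_sites", positive = TRUE)
  check_scalar(blocks_per_condition, "blocks_per_condition", positive = TRUE)
  if (!all(TASK_LEVELS %in% names(amplitude_by_condition))) {
    abort("`amplitude_by_condition` must name all of 0-back, 1-back, 2-back.")
  }
  if (any(!is.finite(amplitude_by_condition))) abort("condition amplitudes must be finite.")
  if (informative_fraction <= 0 || informative_fraction > 1) {
    abort("`informative_fraction` must be in (0, 1].")
  }
  if (hbr_ratio <= 0 || hbr_ratio > 1) abort("`hbr_ratio` must be in (0, 1].")
  freqs <- c(noise$cardiac$freq, noise$respiration$freq, noise$mayer$freq)
  if (any(freqs >= fs / 2)) {
    abort("noise center frequencies must lie below the Nyquist frequency fs/2.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_sites = as.integer(n_sites),
      fs = fs, block_seconds = block_seconds, rest_seconds = rest_seconds,
      blocks_per_condition = as.integer(blocks_per_condition),
      condition_order = condition_order,
      amplitude_by_condition = amplitude_by_condition[TASK_LEVELS],
      hbr_ratio = hbr_ratio, informative_fraction = informative_fraction,
      noise = noise, subject_gain_sd = subject_gain_sd,
      hrf_peak = hrf_peak, hrf_undershoot = hrf_undershoot, hrf_ratio = hrf_ratio,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' Physiological noise components for the session simulator
#'
#' Amplitudes are micromolar; center frequencies Hz. The defaults are standard
#' physiological values for adult prefrontal fNIRS, not estimates from any
#' particular dataset. Set any amplitude (or the white-noise SD) to zero to
#' disable that component.
#'
#' @param cardiac,respiration,mayer Lists with `amplitude` and `freq` for the
#'   sinusoidal components (random phase per channel).
#' @param drift List with `amplitude` of the slow drift (a random-period
#'   60-180 s sinusoid plus a random linear ramp per channel).
#' @param white List with `sd` of additive white Gaussian noise.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(cardiac = list(amplitude = 0.25, freq = 1.1),
                         respiration = list(amplitude = 0.25, freq = 0.25),
                         mayer = list(amplitude = 0.3, freq = 0.1),
                         drift = list(amplitude = 0.4),
                         white = list(sd = 0.3)) {
  structure(
    list(
      cardiac = cardiac, respiration = respiration, mayer = mayer,
      drift = drift, white = white
    ),
    class = "noise_config"
  )
}

#' Silence all noise components
#'
#' Convenience constructor for noise-free simulations (signal-only recordings).
#' @return A `noise_config` with every amplitude and SD set to zero.
#' @export
noise_off <- function() {
  noise_config(
    cardiac = list(amplitude = 0, freq = 1.1),
    respiration = list(amplitude = 0, freq = 0.25),
    mayer = list(amplitude = 0, freq = 0.1),
    drift = list(amplitude = 0),
    white = list(sd = 0)
  )
}

#' Simulate one labelled fNIRS session
#'
#' Generates a block-design n-back session for one subject: informative HbO2
#' channels carry a condition-amplitude boxcar convolved with the canonical
#' double-gamma HRF (area-normalized, so block plateaus approach the condition
#' amplitude); paired HbR channels carry `-hbr_ratio` times the same task
#' component with independent noise; non-informative sites carry noise only.
#' Which sites are informative is drawn once from the root seed (shared by all
#' subjects); everything subject-specific (block order, gain, noise) comes
#' from a per-subject derived stream, so the same `(config, subject)` always
#' yields a bit-identical recording.
#'
#' @param config A [sim_config()].
#' @param subject Positive integer subject index.
#' @return An object of class `fnirs_recording`: list with `data`
#'   (channels x samples matrix, micromolar), `channels` (tibble: channel,
#'   site, chromophore, informative), `fs`, `condition_track` (per-sample
#'   label in rest/0-back/1-back/2-back) and `subject_id`.
#' @export
simulate_session <- function(config, subject) {
  stopifnot(inherits(config, "sim_config"))
  check_scalar(subject, "subject", positive = TRUE)

  n_sites <- config$n_sites
  n_inf <- max(1L, round(config$informative_fraction * n_sites))
  ## site informativeness is a property of the dataset, not the subject
  informative_sites <- with_seed_local(derive_seed(config$seed, "sites"), {
    sort(sample.int(n_sites, n_inf))
  })

  ## block timeline: leading rest, then task block + rest, per block
  n_blocks <- 3L * config$blocks_per_condition
  seg_task <- seconds_to_samples(config$block_seconds, config$fs)
  seg_rest <- seconds_to_samples(config$rest_seconds, config$fs)

  subj_seed <- derive_seed(config$seed, "subject", subject)
  rec <- with_seed_local(subj_seed, {
    order <- rep(TASK_LEVELS, config$blocks_per_condition)
    if (config$condition_order == "shuffled") order <- sample(order)

    track <- rep("rest", seg_rest)
    for (b in order) track <- c(track, rep(b, seg_task), rep("rest", seg_rest))
    n <- length(track)
    t_sec <- (seq_len(n) - 1) / config$fs

    ## task regressor: amplitude boxcar (*) area-normalized HRF
    amps <- config$amplitude_by_condition
    box <- ifelse(track == "rest", 0, amps[track])
    kernel <- double_gamma_hrf(config$fs, 30,
      peak_delay = config$hrf_peak,
      undershoot_delay = config$hrf_undershoot,
      undershoot_ratio = config$hrf_ratio
    )
    kernel <- kernel / sum(kernel)
    response <- stats::convolve(box, rev(kernel), type = "open")[seq_len(n)]

    gain <- max(0.2, 1 + rnorm(1, 0, config$subject_gain_sd))

    n_ch <- 2L * n_sites
    site_of <- rep(seq_len(n_sites), each = 2L)
    chrom <- rep(c("HbO2", "HbR"), n_sites)
    inf_site <- site_of %in% informative_sites

    signal <- matrix(0, n_ch, n)
    task_rows <- which(inf_site)
    for (r in task_rows) {
      s <- if (chrom[r] == "HbO2") gain else -config$hbr_ratio * gain
      signal[r, ] <- s * response
    }

    data <- signal + noise_matrix(config$noise, n_ch, t_sec)

    channels <- tibble::tibble(
      channel = seq_len(n_ch), site = site_of, chromophore = chrom,
      informative = inf_site,
      name = paste0("S", site_of, "_", chrom)
    )
    new_recording(data, channels, config$fs, track,
      subject_id = paste0("sub-", formatC(subject, width = 2, flag = "0"))
    )
  })
  rec
}

#' Simulate a multi-subject dataset
#'
#' @param config A [sim_config()].
#' @param subjects Integer subject indices; defaults to
#'   `1:config$n_subjects`.
#' @return Named list of `fnirs_recording` objects.
#' @export
simulate_dataset <- function(config, subjects = seq_len(config$n_subjects)) {
  recs <- lapply(subjects, function(s) simulate_session(config, s))
  names(recs) <- vapply(recs, function(r) r$subject_id, character(1))
  recs
}

## additive noise for all channels at once; one RNG draw order, fixed
noise_matrix <- function(noise, n_ch, t_sec) {
  n <- length(t_sec)
  out <- matrix(0, n_ch, n)
  sinusoid <- function(amplitude, freq) {
    if (amplitude == 0) {
      return(NULL)
    }
    phase <- runif(n_ch, 0, 2 * pi)
    amplitude * sin(outer(phase, 2 * pi * freq * t_sec, `+`))
  }
  for (comp in list(noise$cardiac, noise$respiration, noise$mayer)) {
    m <- sinusoid(comp$amplitude, comp$freq)
    if (!is.null(m)) out <- out + m
  }
  if (noise$drift$amplitude > 0) {
    period <- runif(n_ch, 60, 180)
    phase <- runif(n_ch, 0, 2 * pi)
    slope <- runif(n_ch, -0.5, 0.5)
    slow <- sin(phase + (2 * pi / period) %o% t_sec)
    ramp <- slope %o% (t_sec / max(t_sec[n], 1))
    out <- out + noise$drift$amplitude * (slow + ramp)
  }
  if (noise$white$sd > 0) {
    out <- out + matrix(rnorm(n_ch * n, 0, noise$white$sd), n_ch, n)
  }
  out
}

new_recording <- function(data, channels, fs, condition_track, subject_id) {
  stopifnot(
    is.matrix(data), nrow(data) == nrow(channels),
    ncol(data) == length(condition_track), all(is.finite(data))
  )
  structure(
    list(
      data = data, channels = channels, fs = fs,
      condition_track = condition_track, subject_id = subject_id
    ),
    class = "fnirs_recording"
  )
}

#' @export
print.fnirs_recording <- function(x, ...) {
  n_task <- sum(x$condition_track != "rest")
  cat(sprintf(
    "<fnirs_recording %s: %d channels x %d samples @ %.3f Hz (%.0f s, %d task samples)>\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, n_task
  ))
  invisible(x)
}

## local seed helper: evaluates `code` under `seed` without touching the
## caller's RNG state
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
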