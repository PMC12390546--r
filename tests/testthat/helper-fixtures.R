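# Shared fixtures: everything is generated in code at test time.

# a small, fast simulation: 8 sites (16 channels), short session
tiny_sim <- function(seed = 1, n_subjects = 2, n_sites = 8,
                     noise = noise_config(), ...) {
  sim_config(
    n_subjects = n_subjects, n_sites = n_sites, blocks_per_condition = 2,
    block_seconds = 20, rest_seconds = 8, noise = noise, seed = seed, ...
  )
}

# hand-built recording with an exactly controlled condition track
make_recording <- function(track, n_channels = 2, fs = 8.138,
                           data = NULL, subject_id = "sub-test") {
  n <- length(track)
  if (is.null(data)) {
    data <- matrix(seq_len(n_channels * n), n_channels, n)
  }
  channels <- tibble::tibble(
    channel = seq_len(n_channels),
    site = rep(seq_len(ceiling(n_channels / 2)), each = 2)[seq_len(n_channels)],
    chromophore = rep(c("HbO2", "HbR"), length.out = n_channels),
    informative = TRUE,
    name = paste0("ch", seq_len(n_channels))
  )
  fnirsload:::new_recording(data, channels, fs, track, subject_id)
}

# condition track made of labelled runs: runs = list(c(label, length), ...)
make_track <- function(...) {
  runs <- list(...)
  unlist(lapply(runs, function(r) rep(r[[1]], as.integer(r[[2]]))))
}

# toy window set: two or three constant-signal classes, trivially separable
toy_windows <- function(n_per_class = 10, n_channels = 4, n_samples = 32,
                        classes = c("0-back", "1-back", "2-back"),
                        sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    n <- n_per_class * length(classes)
    labels <- factor(rep(classes, each = n_per_class),
      levels = c("0-back", "1-back", "2-back")
    )
    means <- seq(-1, 1, length.out = length(classes))
    w <- array(rnorm(n * n_channels * n_samples, sd = sd),
      dim = c(n, n_channels, n_samples)
    )
    for (i in seq_len(n)) {
      w[i, , ] <- w[i, , ] + means[as.integer(factor(labels[i], levels = classes))]
    }
    list(x = w, y = droplevels(labels))
  })
}
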