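## Internal helpers: seed derivation and small assertions.

#' Derive a reproducible sub-seed from a root seed
#'
#' Every source of randomness in the package draws from a named stream derived
#' from one root seed, so stages (simulation, fold splitting, weight
#' initialization, shuffling) can be re-run independently and adding subjects
#' or grid cells never perturbs earlier ones. The derivation folds each stream
#' identifier into a Lehmer-style congruential state modulo 2^31 - 1; character
#' identifiers enter via a positional character-code sum. All arithmetic stays
#' below 2^53 so it is exact in doubles, and the result is a strictly positive
#' 31-bit integer suitable for [set.seed()].
#'
#' @param seed Root seed (single number).
#' @param ... Stream identifiers: integers and/or short strings.
#' @return A positive integer scalar.
#' @examples
#' derive_seed(1, "simulate", 3)
#' @export
derive_seed <- function(seed, ...) {
  ids <- list(...)
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m) + 1
  for (id in ids) {
    if (is.character(id)) {
      id <- sum(utf8ToInt(id) * seq_len(nchar(id)))
    }
    id <- abs(as.numeric(id)) %% m
    s <- (s * 48271 + id + 1) %% m
    # second pass decorrelates adjacent integer ids
    s <- (s * 16807 + 12345) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

#' Convert a duration in seconds to a sample count
#'
#' Uses round-half-away-from-zero, the convention required to reproduce the
#' published window lengths at the NIRSIT sampling rate of 8.138 Hz:
#' 10 s -> 81, 20 s -> 163 (floor would give 162), 30 s -> 244 samples.
#'
#' @param seconds Window duration in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0).
#' @return Integer number of samples.
#' @examples
#' seconds_to_samples(20, 8.138) # 163
#' @export
seconds_to_samples <- function(seconds, fs) {
  if (any(!is.finite(seconds)) || any(seconds <= 0)) {
    abort("`seconds` must be positive and finite.")
  }
  if (!is.finite(fs) || fs <= 0) abort("`fs` must be a positive sampling rate in Hz.")
  as.integer(floor(seconds * fs + 0.5))
}

## scalar validation used by the config constructors
check_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (length(x) != 1 || !is.numeric(x) || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

## md5 of an arbitrary R object, via a temporary file (used for pipeline caching)
hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  # version = 2 keeps hashes stable across R >= 3.5
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

TASK_LEVELS <- c("0-back", "1-back", "2-back")
TRACK_LEVELS <- c("rest", TASK_LEVELS)
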