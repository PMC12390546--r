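#' Shuffled k-fold partition
#'
#' Randomly shuffles `n` items and partitions them into `k` folds whose sizes
#' differ by at most one. The assignment depends only on `(n, k, seed)`, so a
#' grid of learning rates evaluated at the same `(window, mode)` reuses
#' byte-identical folds.
#'
#' @param n Number of items (>= k).
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of length `n` with fold ids in `1:k`.
#' @export
kfold_split <- function(n, k = 5, seed = 1) {
  check_scalar(n, "n", positive = TRUE)
  check_scalar(k, "k", positive = TRUE)
  if (n < k) abort(sprintf("cannot split %d items into %d folds.", n, k))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  folds <- integer(n)
  folds[with_seed_local(seed, sample.int(n))] <- rep(seq_len(k), times = sizes)
  folds
}

#' Grouped (subject-wise) k-fold partition
#'
#' Assigns whole groups (e.g. subjects) to folds, shuffled then dealt
#' round-robin, so no group spans a train/test boundary. Provided as the
#' leakage-resistant alternative to the random split; window-level random
#' splitting lets temporally adjacent (especially overlapping) windows of one
#' subject appear on both sides of a fold boundary.
#'
#' @param groups Group id per item.
#' @param k Number of folds (requires at least `k` distinct groups).
#' @param seed RNG seed.
#' @return Integer vector of fold ids per item.
#' @export
grouped_kfold_split <- function(groups, k = 5, seed = 1) {
  u <- unique(groups)
  if (length(u) < k) {
    abort(sprintf("grouped split needs >= %d groups, got %d.", k, length(u)))
  }
  shuffled <- with_seed_local(seed, sample(u))
  fold_of_group <- rep(seq_len(k), length.out = length(u))
  names(fold_of_group) <- as.character(shuffled)
  unname(fold_of_group[as.character(groups)])
}

#' Experiment grid specification
#'
#' The full training protocol for [run_experiment()]: window lengths,
#' segmentation modes, learning rates, epochs, batch size, fold count and
#' feature-selection size. Defaults reproduce the study grid
#' (10/20/30 s x overlap/nonoverlap x LR 0.1/0.01/0.001, 200 epochs,
#' batch 64, 5 folds, top-50 channels).
#'
#' @param window_seconds Window lengths in seconds.
#' @param modes Segmentation modes.
#' @param learning_rates Adam learning rates.
#' @param epochs Training epochs per fold.
#' @param batch_size Minibatch size.
#' @param folds Number of cross-validation folds.
#' @param k_features Channels retained by ANOVA selection.
#' @param step_fraction Overlap-mode step as a fraction of the window.
#' @param reducer Window summary reducer for the ANOVA observations.
#' @param paper_mode If `TRUE`, standardization and feature selection are fit
#'   once on the full dataset before fold splitting (the global-standardization
#'   protocol common in published pipelines; a documented leakage source). Default `FALSE`: both
#'   are fit per fold on training data only.
#' @param grouped_folds Use [grouped_kfold_split()] by subject instead of the
#'   random window-level split.
#' @param seed Root seed; all stage seeds are derived from it.
#' @return A list of class `train_spec`.
#' @export
train_spec <- function(window_seconds = c(10, 20, 30),
                       modes = c("overlap", "nonoverlap"),
                       learning_rates = c(0.1, 0.01, 0.001),
                       epochs = 200, batch_size = 64, folds = 5,
                       k_features = 50, step_fraction = 0.5,
                       reducer = "mean",
                       paper_mode = FALSE, grouped_folds = FALSE, seed = 1) {
  stopifnot(
    all(modes %in% c("overlap", "nonoverlap")),
    folds >= 2, epochs >= 1, batch_size >= 1,
    step_fraction > 0, step_fraction < 1
  )
  structure(
    list(
      window_seconds = window_seconds, modes = modes,
      learning_rates = learning_rates, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), folds = as.integer(folds),
      k_features = as.integer(k_features), step_fraction = step_fraction,
      reducer = reducer, paper_mode = paper_mode,
      grouped_folds = grouped_folds, seed = seed
    ),
    class = "train_spec"
  )
}

#' Run the cross-validated experiment grid
#'
#' End-to-end protocol for every (window length, segmentation mode, learning
#' rate) cell: segment the recordings into pure-label windows, build one
#' shuffled fold partition per (window, mode) — shared across learning rates
#' so they are compared on identical data — then per fold standardize the
#' channels, rank them by one-way ANOVA F on the training windows, keep the
#' top K, train an EEGNet configured for the window length, and score the
#' held-out fold. Cell failures are isolated into the `status` column rather
#' than aborting the grid.
#'
#' @param recordings A list of `fnirs_recording` objects (e.g. from
#'   [simulate_dataset()]).
#' @param spec A [train_spec()].
#' @return A tibble of class `cv_report`: one row per (window, mode, lr,
#'   fold) with metrics, sizes and status. [glance()] aggregates to
#'   mean +/- sd per cell; [autoplot()] draws the learning-rate/mode
#'   interaction. Fold assignments and the spec echo are kept as attributes.
#' @export
run_experiment <- function(recordings, spec = train_spec()) {
  stopifnot(inherits(spec, "train_spec"))
  if (inherits(recordings, "fnirs_recording")) recordings <- list(recordings)
  fs <- recordings[[1]]$fs
  rows <- list()
  fold_maps <- list()

  for (w in spec$window_seconds) {
    for (mode in spec$modes) {
      ws <- segment_windows(recordings, w, mode,
        step_seconds = w * spec$step_fraction
      )
      n <- dim(ws$windows)[1]
      fold_seed <- derive_seed(spec$seed, "folds", round(w * 1000), mode)
      folds <- if (spec$grouped_folds) {
        grouped_kfold_split(ws$meta$recording, spec$folds, fold_seed)
      } else {
        kfold_split(n, spec$folds, fold_seed)
      }
      fold_maps[[paste(w, mode, sep = "_")]] <- folds

      global_prep <- if (spec$paper_mode) prep_fit(ws, spec) else NULL

      for (lr in spec$learning_rates) {
        for (fold in seq_len(spec$folds)) {
          res <- tryCatch(
            run_cell_fold(ws, folds, fold, lr, spec, w, fs, global_prep),
            error = function(e) {
              tibble::tibble(
                accuracy = NA_real_, auc = NA_real_, recall = NA_real_,
                precision = NA_real_, f1 = NA_real_,
                n_train = NA_integer_, n_test = NA_integer_,
                status = paste("failed:", conditionMessage(e))
              )
            }
          )
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble::tibble(
              window_seconds = w, mode = mode, lr = lr, fold = fold
            ),
            res
          )
        }
      }
    }
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "spec") <- spec
  attr(report, "fold_maps") <- fold_maps
  class(report) <- c("cv_report", class(report))
  report
}

## fit the fold-local (or global) preprocessing: ANOVA selection, then a
## scaler on the retained channels. Selection runs on raw summaries — the F
## statistic is invariant under the per-channel affine standardization, so
## ranking before scaling is equivalent and avoids standardizing channels
## that are about to be dropped.
prep_fit <- function(ws_fit, spec) {
  summ <- channel_summary(ws_fit, reducer = spec$reducer)
  scores <- anova_f_scores(summ, ws_fit$labels)
  sel <- select_top_k(scores, spec$k_features)
  scaler <- fit_scaler(subset_windows(ws_fit, channels = sel$indices),
    eps = 1e-12
  )
  list(selection = sel, scaler = scaler)
}

run_cell_fold <- function(ws, folds, fold, lr, spec, w, fs, global_prep) {
  test_idx <- which(folds == fold)
  train_idx <- which(folds != fold)
  ws_train <- subset_windows(ws, train_idx)
  ws_test <- subset_windows(ws, test_idx)

  prep <- global_prep %||% prep_fit(ws_train, spec)
  sel <- prep$selection$indices

  xtr <- apply_scaler(prep$scaler, subset_windows(ws_train, channels = sel))
  xte <- apply_scaler(prep$scaler, subset_windows(ws_test, channels = sel))

  cfg <- eegnet_config(w, fs = fs, n_channels = length(sel))
  seed <- derive_seed(
    spec$seed, "train", round(w * 1000), unique(ws$meta$mode)[1],
    round(lr * 1e6), fold
  )
  model <- eegnet_init(cfg, seed = derive_seed(seed, "init"))
  model <- train_eegnet(model, xtr,
    lr = lr, epochs = spec$epochs,
    batch_size = spec$batch_size, seed = derive_seed(seed, "sgd")
  )
  if (model$status != "ok") {
    return(tibble::tibble(
      accuracy = NA_real_, auc = NA_real_, recall = NA_real_,
      precision = NA_real_, f1 = NA_real_,
      n_train = length(train_idx), n_test = length(test_idx),
      status = model$status
    ))
  }
  metrics <- evaluate_model(model, xte)
  dplyr::bind_cols(
    metrics,
    tibble::tibble(
      n_train = length(train_idx), n_test = length(test_idx), status = "ok"
    )
  )
}

#' @export
tidy.cv_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.cv_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$window_seconds, .data$mode, .data$lr) |>
    dplyr::summarise(
      dplyr::across(
        c("accuracy", "auc", "recall", "precision", "f1"),
        list(mean = mean, sd = stats::sd)
      ),
      n_folds = dplyr::n(), .groups = "drop"
    )
}

#' @export
summary.cv_report <- function(object, ...) {
  g <- glance(object)
  fmt <- function(m, s) sprintf("%.4f ± %.4f", m, ifelse(is.na(s), 0, s))
  out <- tibble::tibble(
    `Window Size` = sprintf("%g s", g$window_seconds),
    Mode = g$mode,
    `Learning Rate` = g$lr,
    Accuracy = fmt(g$accuracy_mean, g$accuracy_sd),
    AUC = fmt(g$auc_mean, g$auc_sd),
    Recall = fmt(g$recall_mean, g$recall_sd),
    Precision = fmt(g$precision_mean, g$precision_sd),
    `F1-Score` = fmt(g$f1_mean, g$f1_sd)
  )
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report: %d grid cells x %d folds>\n",
    nrow(unique(tibble::as_tibble(x)[c("window_seconds", "mode", "lr")])),
    attr(x, "spec")$folds
  ))
  print(summary(x))
  invisible(x)
}
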