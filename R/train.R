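#' Train an EEGNet model with Adam and cross-entropy loss
#'
#' Minibatch training: each epoch shuffles the training windows, iterates
#' batches of `batch_size` (the final partial batch included), takes an Adam
#' step (betas 0.9/0.999, epsilon 1e-8, no weight decay) on the
#' cross-entropy loss, and re-projects the max-norm-constrained spatial
#' filters after every step. No early stopping, learning-rate schedule or
#' validation checkpointing is applied: the final-epoch model is returned.
#' Deterministic given `seed`. A non-finite loss aborts training and is
#' recorded in `status` rather than raised.
#'
#' @param model An `eegnet` from [eegnet_init()].
#' @param x Training inputs: array `[n, channels, samples]` or a
#'   `fnirs_windows`.
#' @param y Class labels (factor or character), one per window; ignored when
#'   `x` is a `fnirs_windows` carrying labels.
#' @param lr Learning rate. `lr = 0` performs null steps: weights are
#'   returned unchanged.
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size (the study default is 64).
#' @param seed Seed governing shuffling and dropout.
#' @return The trained `eegnet`, with `loss_trace` (mean cross-entropy per
#'   epoch) and `status` (`"ok"` or `"diverged"`) attached.
#' @export
train_eegnet <- function(model, x, y = NULL, lr = 0.001, epochs = 200,
                         batch_size = 64, seed = 1) {
  stopifnot(inherits(model, "eegnet"))
  if (inherits(x, "fnirs_windows")) {
    y <- x$labels
    x <- x$windows
  }
  y <- droplevels(as.factor(y))
  n <- dim(x)[1]
  if (length(y) != n) abort("one label per training window is required.")
  yi <- as.integer(factor(as.character(y), levels = TASK_LEVELS[seq_len(model$config$n_classes)]))
  if (anyNA(yi)) abort("labels outside the model's class set.")

  opt <- adam_new(model$params)
  trace <- numeric(epochs)
  status <- "ok"
  with_seed_local(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- x[idx, , , drop = FALSE]
        fwd <- eegnet_forward(model, xb, training = TRUE, keep_cache = TRUE)
        lp <- t(fwd$logp) # [N, B]
        b <- length(idx)
        loss <- -mean(lp[cbind(yi[idx], seq_len(b))])
        if (!is.finite(loss)) {
          status <- "diverged"
          break
        }
        losses <- c(losses, loss)
        ## d(cross-entropy)/d(logits) = (softmax - onehot) / batch
        dlogits <- exp(lp)
        dlogits[cbind(yi[idx], seq_len(b))] <-
          dlogits[cbind(yi[idx], seq_len(b))] - 1
        dlogits <- dlogits / b
        grads <- eegnet_backward(model, fwd$cache, dlogits)
        if (lr > 0) {
          st <- adam_step(opt, model$params, grads, lr)
          opt <- st$opt
          model$params <- st$params
          model <- apply_max_norm(model)
        }
      }
      if (status != "ok") break
      trace[ep] <- mean(losses)
    }
  })
  model$loss_trace <- if (status == "ok") trace else trace[trace != 0]
  model$status <- status
  model
}

adam_new <- function(params) {
  list(
    t = 0,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

adam_step <- function(opt, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(opt = opt, params = params)
}

#' Classification metrics for multi-class predictions
#'
#' Accuracy plus macro-averaged recall, precision and F1 over the classes
#' present in the truth, and macro one-vs-rest AUC from class probabilities
#' (per-class Mann-Whitney statistic with midranks; classes absent from the
#' truth are skipped with a warning). Precision of a never-predicted class is
#' defined as 0.
#'
#' @param truth Factor of true labels.
#' @param pred Factor of predicted labels (same levels).
#' @param prob Optional n x classes probability matrix (columns in level
#'   order) for the AUC; omit to get `NA` AUC.
#' @return A one-row tibble: accuracy, auc, recall, precision, f1.
#' @export
classification_metrics <- function(truth, pred, prob = NULL) {
  truth <- as.factor(truth)
  pred <- factor(as.character(pred), levels = levels(truth))
  present <- levels(truth)[levels(truth) %in% unique(as.character(truth))]
  if (length(present) < nlevels(truth)) {
    warn(sprintf(
      "class(es) absent from the truth: %s; macro metrics cover present classes only.",
      paste(setdiff(levels(truth), present), collapse = ", ")
    ))
  }
  acc <- mean(as.character(pred) == as.character(truth))
  per <- vapply(present, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(rec, prec, f1)
  }, numeric(3))
  auc <- if (is.null(prob)) NA_real_ else macro_ovr_auc(truth, prob, present)
  tibble::tibble(
    accuracy = acc, auc = auc,
    recall = mean(per[1, ]), precision = mean(per[2, ]), f1 = mean(per[3, ])
  )
}

## one-vs-rest AUC per class via the rank-sum (Mann-Whitney) statistic
macro_ovr_auc <- function(truth, prob, present) {
  aucs <- vapply(present, function(cl) {
    j <- match(cl, levels(truth))
    pos <- truth == cl
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      return(NA_real_)
    }
    r <- rank(prob[, j]) # midranks handle ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Evaluate a trained model on held-out windows
#'
#' @param model A trained `eegnet`.
#' @param x Test inputs (array or `fnirs_windows`).
#' @param y Test labels (taken from `x` if it is a `fnirs_windows`).
#' @return A one-row tibble of metrics (see [classification_metrics()]).
#' @export
evaluate_model <- function(model, x, y = NULL) {
  if (inherits(x, "fnirs_windows")) {
    y <- x$labels
    x <- x$windows
  }
  y <- factor(as.character(y), levels = TASK_LEVELS[seq_len(model$config$n_classes)])
  prob <- predict(model, x, type = "prob")
  pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
    levels = levels(y)
  )
  classification_metrics(y, pred, prob)
}
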