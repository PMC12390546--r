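# closed-form parameter count, independent of the builder
oracle_params <- function(cfg) {
  M <- cfg$F1 * cfg$D
  cfg$F1 * cfg$kernel1 + 2 * cfg$F1 + # temporal conv + bn
    M * cfg$n_channels + 2 * M + # spatial depthwise + bn
    M * cfg$kernel2 + cfg$F2 * M + 2 * cfg$F2 + # separable + bn
    cfg$n_classes * cfg$F2 * cfg$t2 + cfg$n_classes # classifier
}

test_that("window-scaled hyperparameters satisfy F2 = F1 x D everywhere", {
  withr::with_seed(41, {
    for (w in c(5, 10, 14, 20, 27, 30, 45)) {
      cfg <- eegnet_config(w, n_channels = 10)
      expect_equal(cfg$F2, cfg$F1 * cfg$D)
      expect_equal(cfg$D, 2L)
    }
  })
})

test_that("off-grid window lengths take the nearest tabulated configuration", {
  expect_equal(eegnet_config(12, n_channels = 8)$F1, 8L) # nearest 10 s
  expect_equal(eegnet_config(26, n_channels = 8)$F1, 32L) # nearest 30 s
  cfg <- eegnet_config(30, n_channels = 8, kernel2_fixed = TRUE)
  expect_equal(cfg$kernel2, 16L) # layer-table constant instead of scaled 32
})

test_that("inputs too short for the pooling chain are rejected at build time", {
  expect_error(eegnet_config(3, fs = 8.138), "32")
  expect_silent(eegnet_config(10, n_channels = 4, n_samples = 32))
})

test_that("forward pass realizes the tabulated shapes for randomized configs", {
  withr::with_seed(42, {
    for (i in 1:5) {
      C <- sample(4:12, 1)
      T0 <- sample(32:120, 1)
      B <- sample(2:5, 1)
      cfg <- eegnet_config(sample(c(10, 20, 30), 1), n_channels = C, n_samples = T0)
      m <- eegnet_init(cfg, i)
      out <- fnirsload:::eegnet_forward(m, array(rnorm(B * C * T0), c(B, C, T0)))
      M <- cfg$F1 * cfg$D
      expect_equal(out$shapes$block1, c(B, M, 1, T0 %/% 4))
      expect_equal(out$shapes$block2, c(B, cfg$F2, 1, (T0 %/% 4) %/% 8))
      expect_equal(dim(out$logp), c(B, 3))
      # log-softmax rows are normalized log-probabilities
      expect_equal(rowSums(exp(out$logp)), rep(1, B), tolerance = 1e-6)
      expect_equal(eegnet_n_params(m), oracle_params(cfg))
      expect_equal(attr(eegnet_shapes(cfg), "total_params"), oracle_params(cfg))
    }
  })
})

test_that("Xavier-uniform draws respect the fan bounds; batchnorm starts at (1, 0)", {
  cfg <- eegnet_config(10, n_channels = 20)
  m <- eegnet_init(cfg, 7)
  bounds <- list(
    W1 = sqrt(6 / (cfg$kernel1 + cfg$F1 * cfg$kernel1)),
    W2 = sqrt(6 / (20 + cfg$F1 * cfg$D * 20)),
    W3 = sqrt(6 / (cfg$kernel2 + cfg$F1 * cfg$D * cfg$kernel2)),
    W4 = sqrt(6 / (cfg$F1 * cfg$D + cfg$F2)),
    W5 = sqrt(6 / (cfg$F2 * cfg$t2 + cfg$n_classes * cfg$t2))
  )
  for (nm in names(bounds)) {
    w <- m$params[[nm]]
    expect_lte(max(abs(w)), bounds[[nm]])
    expect_gt(max(abs(w)), 0.8 * bounds[[nm]]) # the draw actually fills the box
  }
  expect_equal(m$params$gamma1, rep(1, cfg$F1))
  expect_equal(m$params$beta3, rep(0, cfg$F2))
  expect_equal(m$params$b5, rep(0, 3))
  expect_identical(m$params, eegnet_init(cfg, 7)$params)
  expect_false(identical(m$params, eegnet_init(cfg, 8)$params))
})

test_that("max-norm projection rescales only filters outside the unit ball", {
  cfg <- eegnet_config(10, n_channels = 16)
  m <- eegnet_init(cfg, 1)
  m$params$W2[1, ] <- m$params$W2[1, ] * 0.5 / sqrt(sum(m$params$W2[1, ]^2))
  m$params$W2[2, ] <- m$params$W2[2, ] * 4 / sqrt(sum(m$params$W2[2, ]^2))
  before <- m$params$W2[1, ]
  m2 <- apply_max_norm(m)
  expect_identical(m2$params$W2[1, ], before) # inside: untouched
  expect_equal(sqrt(sum(m2$params$W2[2, ]^2)), 1, tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences on every tensor", {
  cfg <- eegnet_config(10, n_channels = 4, n_samples = 32, dropout = 0)
  m <- eegnet_init(cfg, 2)
  withr::with_seed(3, {
    x <- array(rnorm(3 * 4 * 32), c(3, 4, 32))
  })
  y <- c(1L, 2L, 3L)
  loss_fn <- function(model) {
    lp <- t(fnirsload:::eegnet_forward(model, x, training = TRUE)$logp)
    -mean(lp[cbind(y, 1:3)])
  }
  fwd <- fnirsload:::eegnet_forward(m, x, training = TRUE, keep_cache = TRUE)
  lp <- t(fwd$logp)
  dlog <- exp(lp)
  dlog[cbind(y, 1:3)] <- dlog[cbind(y, 1:3)] - 1
  dlog <- dlog / 3
  gr <- fnirsload:::eegnet_backward(m, fwd$cache, dlog)
  eps <- 1e-5
  withr::with_seed(9, {
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (i in sample(length(p), min(4, length(p)))) {
        up <- m
        up$params[[nm]][i] <- up$params[[nm]][i] + eps
        dn <- m
        dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
        num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("permuting input channels with the spatial filters leaves outputs unchanged", {
  cfg <- eegnet_config(10, n_channels = 6, n_samples = 40, dropout = 0)
  m <- eegnet_init(cfg, 5)
  withr::with_seed(6, {
    x <- array(rnorm(4 * 6 * 40), c(4, 6, 40))
    perm <- sample(6)
  })
  m2 <- m
  m2$params$W2 <- m$params$W2[, perm]
  out1 <- fnirsload:::eegnet_forward(m, x)$logp
  out2 <- fnirsload:::eegnet_forward(m2, x[, perm, , drop = FALSE])$logp
  expect_equal(out1, out2, tolerance = 1e-10)
})

test_that("every tensor with a gradient path receives a nonzero gradient", {
  cfg <- eegnet_config(10, n_channels = 5, n_samples = 32, dropout = 0)
  m <- eegnet_init(cfg, 11)
  withr::with_seed(12, {
    x <- array(rnorm(6 * 5 * 32), c(6, 5, 32))
  })
  y <- rep(1:3, 2)
  fwd <- fnirsload:::eegnet_forward(m, x, training = TRUE, keep_cache = TRUE)
  lp <- t(fwd$logp)
  dlog <- exp(lp)
  dlog[cbind(y, 1:6)] <- dlog[cbind(y, 1:6)] - 1
  gr <- fnirsload:::eegnet_backward(m, fwd$cache, dlog / 6)
  # beta1 is excluded: a per-map constant added before the linear spatial
  # collapse is exactly removed by the following batchnorm, so its gradient
  # is structurally zero (the shift is redundant there, not a dead branch).
  for (nm in setdiff(names(gr), "beta1")) {
    expect_gt(max(abs(gr[[nm]])), 0)
  }
  expect_lt(max(abs(gr$beta1)), 1e-12)
})

test_that("the model fits a two-class constant-signal toy problem to 100%", {
  toy <- toy_windows(
    n_per_class = 10, n_channels = 4, n_samples = 32,
    classes = c("0-back", "1-back"), seed = 44
  )
  cfg <- eegnet_config(10, n_channels = 4, n_samples = 32, n_classes = 2)
  m <- eegnet_init(cfg, 3)
  m <- train_eegnet(m, toy$x, toy$y, lr = 0.001, epochs = 50, batch_size = 10, seed = 4)
  expect_equal(m$status, "ok")
  pred <- predict(m, toy$x)
  expect_equal(mean(as.character(pred) == as.character(toy$y)), 1)
})
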