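# brute-force one-way ANOVA F for a single response vector
oracle_f <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  k <- nlevels(g)
  grand <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (N - k))
}

make_ws <- function(w, labels, fs = 8.138) {
  structure(
    list(
      windows = w,
      labels = factor(labels, levels = c("0-back", "1-back", "2-back")),
      meta = tibble::tibble(
        recording = "sub-x", start = seq_len(dim(w)[1]), mode = "nonoverlap"
      ),
      window_seconds = dim(w)[3] / fs, fs = fs,
      channels = tibble::tibble(
        channel = seq_len(dim(w)[2]), site = seq_len(dim(w)[2]),
        chromophore = "HbO2", informative = TRUE,
        name = paste0("ch", seq_len(dim(w)[2]))
      )
    ),
    class = "fnirs_windows"
  )
}

test_that("channel_summary reduces windows by mean, with closed-form cases", {
  n <- 16
  w <- array(0, c(2, 2, n))
  w[1, 1, ] <- 7 # constant window
  w[2, 2, ] <- 0:(n - 1) # ramp
  ws <- make_ws(w, c("0-back", "1-back"))
  s <- channel_summary(ws)
  expect_equal(unname(s[1, 1]), 7)
  expect_equal(unname(s[2, 2]), (n - 1) / 2)
  withr::with_seed(2, {
    w <- array(rnorm(5 * 3 * 20), c(5, 3, 20))
    ws <- make_ws(w, rep(c("0-back", "1-back", "2-back"), length.out = 5))
    s <- unname(channel_summary(ws))
    for (i in 1:5) {
      for (j in 1:3) expect_equal(s[i, j], mean(w[i, j, ]), tolerance = 1e-12)
    }
  })
})

test_that("equal group means with nonzero spread give F = 0", {
  m <- cbind(c(0, 2, 0, 2, 0, 2)) # every group mean = 1
  sc <- anova_f_scores(m, rep(c("0-back", "1-back", "2-back"), each = 2))
  expect_equal(sc$f_stat, 0)
})

test_that("perfect separation gives an infinite F ranked first", {
  m <- cbind(c(0, 0, 1, 1, 2, 2), rnorm(6))
  sc <- anova_f_scores(m, rep(c("0-back", "1-back", "2-back"), each = 2))
  expect_identical(sc$f_stat[1], Inf)
  expect_equal(sc$rank[1], 1L)
  expect_equal(select_top_k(sc, 1)$indices, 1L)
})

test_that("F and p match the brute-force formula and stats::oneway.test", {
  withr::with_seed(14, {
    g <- rep(c("0-back", "1-back", "2-back"), each = 10)
    m <- matrix(rnorm(30 * 6), 30, 6)
    m[, 2] <- m[, 2] + (as.integer(factor(g)) - 2) * 1.5
    sc <- anova_f_scores(m, g)
    for (j in 1:6) {
      expect_equal(sc$f_stat[j], oracle_f(m[, j], g), tolerance = 1e-10)
      ow <- stats::oneway.test(m[, j] ~ factor(g), var.equal = TRUE)
      expect_equal(sc$f_stat[j], unname(ow$statistic), tolerance = 1e-8)
      expect_equal(sc$p_value[j], unname(ow$p.value), tolerance = 1e-8)
    }
  })
})

test_that("degenerate class sizes are rejected", {
  m <- cbind(rnorm(4))
  expect_error(
    anova_f_scores(m, c("0-back", "0-back", "1-back", "2-back")),
    ">= 2 observations"
  )
  expect_error(anova_f_scores(m, rep("0-back", 4)), "two classes")
})

test_that("top-k selection equals a sort-and-slice oracle, ties by index", {
  withr::with_seed(15, {
    f <- round(runif(120, 0, 5), 1) # coarse grid forces ties
    m <- matrix(0, 12, 120)
    sc <- tibble::tibble(
      channel = seq_along(f), name = as.character(seq_along(f)),
      f_stat = f, p_value = 0.5, rank = NA_integer_
    )
    sc$rank[order(-f, seq_along(f))] <- seq_along(f)
    class(sc) <- c("feature_scores", class(sc))
    got <- select_top_k(sc, 50)$indices
    want <- order(-f, seq_along(f))[1:50]
    expect_identical(got, want)
  })
})

test_that("k = n is the identity selection and k > n warns and keeps all", {
  withr::with_seed(16, {
    m <- matrix(rnorm(60), 12, 5)
    sc <- anova_f_scores(m, rep(c("0-back", "1-back", "2-back"), each = 4))
    expect_setequal(select_top_k(sc, 5)$indices, 1:5)
    expect_warning(sel <- select_top_k(sc, 50), "exceeds")
    expect_equal(sel$k, 5L)
  })
})

test_that("selection is invariant under channel-wise affine rescaling", {
  withr::with_seed(17, {
    g <- rep(c("0-back", "1-back", "2-back"), each = 8)
    m <- matrix(rnorm(24 * 20), 24, 20) +
      outer(as.integer(factor(g)), seq(0, 1, length.out = 20))
    m2 <- sweep(sweep(m, 2, runif(20, 0.1, 5), `*`), 2, rnorm(20), `+`)
    s1 <- select_top_k(anova_f_scores(m, g), 8)$indices
    s2 <- select_top_k(anova_f_scores(m2, g), 8)$indices
    expect_identical(s1, s2)
  })
})

test_that("correlation matrix matches the covariance/sd oracle and is PSD", {
  withr::with_seed(18, {
    m <- matrix(rnorm(40 * 50), 40, 50)
    cm <- correlation_matrix(m)
    # textbook oracle: cov(x, y) / (sd(x) sd(y)) with the n - 1 convention
    oracle <- stats::cov(m) / tcrossprod(apply(m, 2, sd))
    expect_lt(max(abs(cm - oracle)), 1e-10)
    expect_equal(diag(cm), rep(1, 50), ignore_attr = TRUE)
    expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
    expect_equal(cm, t(cm))
    expect_gt(min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  })
})

test_that("self- and anti-correlated columns hit the +/-1 bounds; zero variance flags NaN", {
  x <- rnorm(20)
  cm <- correlation_matrix(cbind(a = x, b = -x))
  expect_equal(cm["a", "a"], 1)
  expect_equal(cm["a", "b"], -1)
  expect_warning(cm2 <- correlation_matrix(cbind(x, rep(1, 20))), "zero-variance")
  expect_true(is.na(cm2[1, 2]))
})

test_that("the selected set is enriched for informative HbO2 channels", {
  cfg <- sim_config(
    n_subjects = 2, n_sites = 40, informative_fraction = 0.3, seed = 19
  )
  recs <- simulate_dataset(cfg)
  ws <- segment_windows(recs, 10, "nonoverlap")
  sel <- select_top_k(anova_f_scores(channel_summary(ws), ws$labels), 20)
  info <- ws$channels$informative[sel$indices]
  hbo <- ws$channels$chromophore[sel$indices] == "HbO2"
  # chance hit-rate for informative channels is the informative fraction
  expect_gt(mean(info), 2 * 0.3)
  # HbO2 carries the larger response, so it should dominate the top of the list
  expect_gt(sum(hbo & info), sum(!hbo & info))
})
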