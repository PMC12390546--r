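# --- seconds -> samples -----------------------------------------------------

test_that("seconds_to_samples rounds half away from zero and rejects bad input", {
  expect_identical(seconds_to_samples(1, 10), 10L)
  expect_identical(seconds_to_samples(0.25, 10), 3L) # 2.5 rounds up, not to even
  expect_error(seconds_to_samples(0, 8.138), "positive")
  expect_error(seconds_to_samples(10, -1), "fs")
})

# --- channel scaler ---------------------------------------------------------

test_that("zero-variance channels are rejected by name, or epsilon-guarded", {
  rec <- make_recording(make_track(list("0-back", 3)),
    data = matrix(c(1, 1, 1, 0, 1, 2), 2, 3, byrow = TRUE)
  )
  expect_error(fit_scaler(rec), "zero-variance channel\\(s\\): 1")
  expect_warning(sc <- fit_scaler(rec, eps = 1e-9), "flooring")
  expect_equal(sc$sigma[1], 1e-9)
})

test_that("two-point channel gives the population-convention mu and sigma", {
  rec <- make_recording(make_track(list("0-back", 2)),
    data = matrix(c(0, 2, 5, 7), 2, 2, byrow = TRUE)
  )
  sc <- fit_scaler(rec)
  expect_equal(sc$mu, c(1, 6))
  expect_equal(sc$sigma, c(1, 1)) # population (n) denominator, not n - 1
})

test_that("applying a fitted scaler standardizes to mean 0, variance 1", {
  withr::with_seed(8, {
    rec <- make_recording(make_track(list("0-back", 200)),
      n_channels = 5,
      data = matrix(rnorm(1000, mean = 3, sd = 4), 5, 200)
    )
    sc <- fit_scaler(rec)
    z <- apply_scaler(sc, rec)
    expect_lt(max(abs(rowMeans(z$data))), 1e-10)
    expect_lt(max(abs(rowMeans(z$data^2) - 1)), 1e-8)
    # algebraic inverse recovers the input
    back <- apply_scaler(sc, z, inverse = TRUE)
    expect_lt(max(abs(back$data - rec$data)), 1e-12)
    # x = mu everywhere -> all zeros
    flat <- rec
    flat$data <- matrix(sc$mu, 5, 200)
    expect_true(all(apply_scaler(sc, flat)$data == 0))
  })
})

test_that("scaling is idempotent only for the identity scaler", {
  withr::with_seed(9, {
    rec <- make_recording(make_track(list("1-back", 50)),
      n_channels = 2, data = matrix(rnorm(100, 2, 3), 2, 50)
    )
    sc <- fit_scaler(rec)
    once <- apply_scaler(sc, rec)
    twice <- apply_scaler(sc, once)
    expect_gt(max(abs(twice$data - once$data)), 0.1)
    ident <- sc
    ident$mu[] <- 0
    ident$sigma[] <- 1
    expect_equal(apply_scaler(ident, rec)$data, rec$data)
  })
})

# --- segmentation -----------------------------------------------------------

fs0 <- 8.138
n10 <- seconds_to_samples(10, fs0) # 81

test_that("a run of exactly 3n samples tiles into 3 disjoint windows", {
  track <- make_track(list("rest", 10), list("1-back", 3 * n10), list("rest", 5))
  ws <- segment_windows(make_recording(track), 10, "nonoverlap")
  expect_equal(dim(ws$windows)[1], 3)
  expect_equal(ws$meta$start - ws$meta$start[1], c(0, 81, 162))
  expect_true(all(ws$labels == "1-back"))
})

test_that("overlap enumeration matches floor((L - n)/step) + 1 with the stated starts", {
  track <- make_track(list("rest", 4), list("2-back", 244), list("rest", 4))
  ws <- segment_windows(make_recording(track), 10, "overlap",
    step_seconds = 41 / fs0
  )
  expect_equal(dim(ws$windows)[1], 4) # floor((244 - 81)/41) + 1
  expect_equal(ws$meta$start - ws$meta$start[1], c(0, 41, 82, 123))
})

test_that("neighbouring overlap windows share exactly n - s samples", {
  track <- make_track(list("0-back", 300))
  ws <- segment_windows(make_recording(track), 10, "overlap",
    step_seconds = 5
  )
  s <- seconds_to_samples(5, fs0)
  starts <- ws$meta$start
  expect_true(all(diff(starts) == s))
  # shared sample indices between consecutive windows
  shared <- (starts[1] + s):(starts[1] + n10 - 1)
  expect_length(shared, n10 - s)
})

test_that("windows are pure-label and never include rest samples", {
  withr::with_seed(21, {
    for (i in 1:5) {
      runs <- lapply(1:6, function(j) {
        list(sample(c("rest", "0-back", "1-back", "2-back"), 1), sample(30:300, 1))
      })
      track <- do.call(make_track, runs)
      rec <- make_recording(track)
      ws <- tryCatch(segment_windows(rec, 3, "nonoverlap"), error = function(e) NULL)
      if (is.null(ws)) next
      n <- dim(ws$windows)[3]
      for (w in seq_len(dim(ws$windows)[1])) {
        seg <- track[ws$meta$start[w] + seq_len(n) - 1]
        expect_true(all(seg == as.character(ws$labels[w])))
      }
    }
  })
})

test_that("window counts match brute-force enumeration over random runs", {
  withr::with_seed(31, {
    for (i in 1:25) {
      L <- sample(20:400, 1)
      n <- sample(10:60, 1)
      s <- sample(1:(n - 1), 1)
      stride <- sample(c(n, s), 1) # nonoverlap or overlap stride
      # brute force: slide a cursor and count fitting windows
      brute <- 0
      at <- 1
      while (at + n - 1 <= L) {
        brute <- brute + 1
        at <- at + stride
      }
      closed <- if (L >= n) (L - n) %/% stride + 1 else 0
      expect_equal(closed, brute)
      track <- make_track(list("1-back", L))
      ws <- tryCatch(
        segment_windows(make_recording(track), n / fs0,
          mode = if (stride == n) "nonoverlap" else "overlap",
          step_seconds = stride / fs0
        ),
        error = function(e) NULL
      )
      got <- if (is.null(ws)) 0 else dim(ws$windows)[1]
      expect_equal(got, brute)
    }
  })
})

test_that("a step at least as long as the window is rejected in overlap mode", {
  track <- make_track(list("1-back", 300))
  expect_error(
    segment_windows(make_recording(track), 10, "overlap", step_seconds = 10),
    "fewer samples"
  )
})

test_that("scaling commutes with segmentation", {
  cfg <- tiny_sim(seed = 13)
  rec <- simulate_session(cfg, 1)
  sc <- fit_scaler(rec)
  a <- segment_windows(apply_scaler(sc, rec), 10, "nonoverlap")
  b <- apply_scaler(sc, segment_windows(rec, 10, "nonoverlap"))
  expect_equal(a$windows, b$windows, tolerance = 1e-12)
})
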