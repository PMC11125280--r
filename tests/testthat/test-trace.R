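test_that("dF/F0 conversion is exact on hand-computed cases", {
  d <- compute_dff(c(10, 10, 10, 12, 11), 1, c(0, 3))
  expect_equal(d$values, c(0, 0, 0, 0.2, 0.1))
  expect_equal(d$f0, 10)

  const <- compute_dff(rep(7, 50), 10, c(0, 2))
  expect_equal(const$values, rep(0, 50))
  expect_equal(const$f0, 7)

  dbl <- compute_dff(c(rep(5, 10), 10), 1, c(0, 10))
  expect_equal(dbl$values[11], 1.0)

  expect_error(compute_dff(c(0, 0, 0, 1), 1, c(0, 3)), "non-positive")
  expect_error(compute_dff(c(-2, -2, 4), 1, c(0, 2)), "non-positive")
})

test_that("dF/F0 is invariant to overall gain of the raw fluorescence", {
  set.seed(4)
  f <- 100 + cumsum(rnorm(200))
  f <- f - min(f) + 1
  a <- compute_dff(f, 30, c(0, 2))
  for (c_gain in c(0.5, 3, 1000)) {
    b <- compute_dff(c_gain * f, 30, c(0, 2))
    expect_equal(b$values, a$values)
  }
})

test_that("Kalman smoothing preserves constants and passes through at gain 1", {
  expect_equal(kalman_smooth(rep(2.5, 100)), rep(2.5, 100))
  set.seed(8)
  x <- rnorm(500)
  expect_equal(kalman_smooth(x, gain = 1), x)
  expect_equal(kalman_smooth(x)[1], x[1])
  expect_length(kalman_smooth(x), 500)
})

test_that("Kalman smoothing reduces white-noise variance, monotonically over passes", {
  set.seed(123)
  x <- rnorm(1e4)
  v0 <- var(x)
  s1 <- kalman_smooth(x)
  s2 <- kalman_smooth(s1)
  s3 <- kalman_smooth(s2)
  expect_lt(var(s1), v0)
  expect_lt(var(s2), var(s1))
  expect_lt(var(s3), var(s2))
})

test_that("trial averaging is the pointwise mean with strict input checks", {
  x <- new_trace <- compute_dff(c(10, 12, 14), 1, c(0, 1))
  avg <- trial_average(list(x, x, x, x, x, x))
  expect_equal(avg$values, x$values)

  expect_equal(trial_average(list(c(1, 2), c(-1, -2)))$values, c(0, 0))
  expect_equal(trial_average(list(c(0, 1), c(0, 3)))$values, c(0, 2))

  expect_error(trial_average(list()), "no traces")
  expect_error(trial_average(list(c(1, 2), c(1, 2, 3))), "length")
})

test_that("trial averaging commutes with dF/F0 when trials share F0", {
  set.seed(31)
  f0 <- 80
  trials <- lapply(1:6, function(i) f0 * (1 + c(rep(0, 30), rnorm(60, 0, 0.1))))
  # force a common baseline so F0 is identical across trials
  for (i in seq_along(trials)) trials[[i]][1:30] <- f0
  d_then_avg <- trial_average(lapply(trials, compute_dff, sampling_rate = 30,
    baseline_window = c(0, 1)))
  avg_then_d <- compute_dff(rowMeans(do.call(cbind, trials)), 30, c(0, 1))
  expect_equal(d_then_avg$values, avg_then_d$values)
})

test_that("dataset-level averaging matches the per-trace reference path", {
  cfg <- tiny_config()
  ds <- simulate_dataset(cfg, seed = 2)
  avg <- average_responses(ds)
  bw <- baseline_window(ds$paradigm)
  # independent route: explicit per-trace compute_dff + trial_average
  for (row in c(1, 5, nrow(avg))) {
    nid <- avg$neuron_id[row]; q <- avg$intensity[row]
    ids <- ds$trials$trace_id[ds$trials$neuron_id == nid &
      ds$trials$intensity == q]
    manual <- trial_average(lapply(ids, function(k)
      compute_dff(ds$f[, k], ds$sampling_rate, bw)))
    expect_equal(avg$dff[[row]], manual$values)
  }
})
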