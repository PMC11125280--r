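test_that("reference curve is the windowed cohort mean", {
  out <- noiseless_avg(n = 1)
  ref <- build_reference(out$avg, out$ds$paradigm,
    sampling_rate = out$ds$sampling_rate)
  idx <- 301:840 # [10, 28) s at 30 Hz
  top <- out$avg$dff[[which(out$avg$intensity == 0.76)]]
  expect_equal(ref$values, top[idx])
  expect_equal(ref$n_contributing, 1)
  expect_equal(ref$source_intensity, 0.76)

  # identical noiseless responders: reference equals the common response
  out4 <- noiseless_avg(n = 4)
  ref4 <- build_reference(out4$avg, out4$ds$paradigm,
    sampling_rate = out4$ds$sampling_rate)
  expect_equal(ref4$values, top[idx], tolerance = 1e-12)
})

test_that("reference recovers a known template within 3 SE under noise", {
  out <- noiseless_avg(n = 1, intensities = 0.76)
  template <- out$avg$dff[[1]]
  idx <- 301:840
  set.seed(77)
  n <- 100
  sigma <- 0.05
  avg <- tibble::tibble(
    neuron_id = seq_len(n), cell_class = "excitatory", intensity = 0.76,
    n_trials = 1L,
    dff = lapply(seq_len(n), function(i) template + rnorm(1800, 0, sigma)))
  ref <- build_reference(avg, out$ds$paradigm, sampling_rate = 30)
  se <- sigma / sqrt(n)
  dev <- abs(ref$values - template[idx]) / se
  # pointwise agreement: RMS deviation at the SE scale, almost all points
  # within 3 SE, none beyond a simultaneous (Bonferroni) bound
  expect_lt(sqrt(mean(dev^2)), 1.5)
  expect_gt(mean(dev < 3), 0.99)
  expect_lt(max(dev), qnorm(1 - 0.001 / length(dev)))
})

test_that("correlation index behaves as a windowed Pearson correlation", {
  out <- noiseless_avg(n = 1)
  ref <- build_reference(out$avg, out$ds$paradigm, sampling_rate = 30)
  top <- out$avg$dff[[which(out$avg$intensity == 0.76)]]
  expect_equal(correlation_index(top, ref), 1.0)
  expect_equal(correlation_index(-top, ref), -1.0)
  expect_equal(correlation_index(top + 0.37, ref), 1.0)
  expect_true(is.na(correlation_index(rep(0.2, 1800), ref)))
})

test_that("correlation index is invariant to positive affine rescaling", {
  out <- noiseless_avg(n = 2)
  ref <- build_reference(out$avg, out$ds$paradigm, sampling_rate = 30)
  set.seed(5)
  v <- out$avg$dff[[2]] + rnorm(1800, 0, 0.02)
  r0 <- correlation_index(v, ref)
  for (a in c(0.2, 5)) for (b in c(-1, 0.3))
    expect_equal(correlation_index(a * v + b, ref), r0)
})

test_that("threshold classification is strict at +-0.2 and handles NA", {
  expect_equal(classify_correlation(c(0.35, -0.21, 0.2, -0.2, NA, 0)),
    c("positive", "negative", "none", "none", "none", "none"))
  cfg <- classifier_config(threshold_pos = 0.9)
  expect_equal(classify_correlation(0.5, cfg), "none")
  expect_error(classifier_config(threshold_neg = 0.1), "threshold")
})

test_that("six-train peak amplitude matches a brute-force epoch scan", {
  p <- make_paradigm("multi_train", 0.76)
  flat <- peak_amplitude(rep(0, 1800), p, correlation_value = 0.5)
  expect_equal(flat$amplitude, 0)
  expect_equal(flat$peaks, rep(0, 6))

  nr <- quiet_population()[1, ]
  f <- simulate_trial(nr, p, 30, seed = 1)
  dff <- (f - nr$f0) / nr$f0
  got <- peak_amplitude(dff, p, correlation_value = 0.9)
  # independent scan: max - min over each 3 s train epoch
  t <- (seq_len(1800) - 1) / 30
  oracle <- vapply(train_onsets(p), function(on) {
    seg <- dff[t >= on & t < on + 3]
    max(seg) - min(seg)
  }, double(1))
  expect_equal(got$peaks, oracle)
  expect_equal(got$amplitude, mean(oracle))
  # the sign rule: negative correlation flips the amplitude sign
  neg <- peak_amplitude(dff, p, correlation_value = -0.5)
  expect_equal(neg$amplitude, -mean(oracle))

  expect_error(peak_amplitude(dff, make_paradigm("long_train", 0.46), 0.5),
    "six-train")
})

test_that("3-10 s peak area follows the baseline-0 and 10% rules", {
  fs <- 30
  n <- 12 * fs + 1
  t <- (seq_len(n) - 1) / fs
  expect_equal(auc_3_10(rep(0, n), fs), 0)

  # triangle of height 1, base 2 s, fully inside the window: area 1
  tri <- pmax(0, 1 - abs(t - 6))
  expect_equal(auc_3_10(tri, fs), 1.0, tolerance = 1e-9)

  # a secondary peak below 10% of the min-max distance is ignored
  small <- pmax(0, 0.05 * (1 - abs(t - 9) / 0.5))
  both <- tri + small
  expect_equal(auc_3_10(both, fs), auc_3_10(tri, fs), tolerance = 1e-9)
  # brute-force check of the threshold arithmetic
  w <- both[t >= 3 & t <= 10]
  expect_lt(0.05, min(w) + 0.1 * (max(w) - min(w)))

  expect_error(auc_3_10(rep(0, 100), fs), "too short")
})

test_that("classification fractions round half away from zero and sum to 100", {
  prof <- tibble::tibble(
    intensity = rep(0.42, 199),
    label = c(rep("positive", 104), rep("negative", 3), rep("none", 92)))
  fr <- classification_fractions(prof)
  expect_equal(fr$pct_pos, 52.3)
  expect_equal(fr$n_total, 199)

  set.seed(19)
  prof2 <- tibble::tibble(
    intensity = sample(c(0.16, 0.76), 500, TRUE),
    label = sample(c("positive", "negative", "none"), 500, TRUE))
  fr2 <- classification_fractions(prof2)
  expect_true(all(abs(fr2$pct_pos + fr2$pct_neg + fr2$pct_none - 100) <= 0.15))
})

test_that("intensity fit recovers exact and degenerate lines", {
  pts <- tibble::tibble(intensity = c(0.1, 0.2, 0.5, 0.7),
    correlation_value = 2 * c(0.1, 0.2, 0.5, 0.7) + 1)
  fit <- intensity_fit(pts)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  const <- intensity_fit(tibble::tibble(intensity = 1:5,
    correlation_value = rep(0.3, 5)))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)

  expect_error(intensity_fit(pts[1:2, ]), "at least 3")

  td <- generics::tidy(fit)
  expect_equal(td$estimate[td$term == "slope"], 2)
  gl <- generics::glance(fit)
  expect_equal(gl$r.squared, 1)
})

test_that("intensity fit recovers a known slope from noisy synthetic points", {
  set.seed(101)
  x <- c(0.16, 0.29, 0.42, 0.5, 0.59, 0.68, 0.76)
  y <- 0.3 * x + rnorm(7, 0, 0.02)
  fit <- intensity_fit(tibble::tibble(intensity = x, correlation_value = y))
  expect_lt(abs(fit$slope - 0.3), 0.1)
})

test_that("rank tests match exact enumeration and behave under shifts", {
  expect_equal(rank_compare(c(1, 2, 3), c(1, 2, 3), paired = TRUE), 1)

  # complete separation at n = m = 10: exact two-sided tail for U = 0,
  # verified against a brute-force enumeration of all rank splits
  a <- 1:10
  b <- 11:20
  p_obs <- rank_compare(a, b)
  combos <- utils::combn(20L, 10L)
  usum <- colSums(matrix(rank(c(a, b))[combos], nrow = 10L))
  u <- usum - 10 * 11 / 2
  p_exact <- 2 * mean(u <= 0)
  expect_equal(p_obs, p_exact)

  # p decreases as the shift between seeded samples grows
  set.seed(55)
  base <- rnorm(30)
  ps <- vapply(c(0.2, 1, 3), function(sh)
    rank_compare(base, base + sh), double(1))
  expect_true(all(diff(ps) < 0))

  expect_warning(p_tied <- rank_compare(rep(1, 5), rep(1, 7)), "tied")
  expect_true(is.na(p_tied))
})

test_that("cohort bookkeeping helpers do the printed arithmetic", {
  expect_equal(unique_neuron_count(219, 189, 25), 383)
  expect_equal(top_fraction_count(335), 34L)
  expect_equal(top_fraction_count(100, 0.25), 25L)
  prof <- tibble::tibble(neuron_id = 1:10, auc_3_10 = c(5, 1:9))
  top <- select_top_fraction(prof, "auc_3_10", 0.2)
  expect_equal(nrow(top), 2)
  expect_equal(top$auc_3_10, c(9, 8))
})
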