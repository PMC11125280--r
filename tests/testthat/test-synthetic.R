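test_that("population sampling honours counts, fractions and the sign rule", {
  pop <- sample_population(100, 0, 1.0, seed = 3)
  expect_equal(nrow(pop), 100)
  expect_true(all(pop$responsive))
  expect_true(all(pop$response_sign == 1))

  expect_equal(nrow(sample_population(0, 0, 0.5, seed = 3)), 0)

  a <- sample_population(80, 20, 0.5, seed = 42)
  b <- sample_population(80, 20, 0.5, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$response_sign[a$cell_class == "inhibitory"] == -1))

  expect_error(sample_population(-1, 0, 0.5), "counts")
})

test_that("a null-model neuron yields a constant trace at F0", {
  nr <- quiet_population()[1, ]
  nr$response_gain <- 0
  p <- make_paradigm("multi_train", 0.76)
  f <- simulate_trial(nr, p, sampling_rate = 30, seed = 1)
  expect_length(f, 1800)
  expect_equal(as.numeric(f), rep(nr$f0, 1800))
})

test_that("a noiseless responder peaks once per pulse train", {
  nr <- quiet_population()[1, ]
  nr$response_gain <- 2
  p <- make_paradigm("multi_train", 0.76)
  f <- simulate_trial(nr, p, sampling_rate = 30, seed = 1)
  dff <- (f - nr$f0) / nr$f0
  # brute-force scan for strict local maxima of the noiseless signal
  n <- length(dff)
  locmax <- which(dff[2:(n - 1)] > dff[1:(n - 2)] &
    dff[2:(n - 1)] > dff[3:n]) + 1L
  t_max <- (locmax - 1) / 30
  onsets <- train_onsets(p)
  epoch <- p$train_duration_s + p$train_interval_s
  in_epoch <- vapply(onsets, function(on)
    sum(t_max >= on & t_max < on + epoch), integer(1))
  expect_equal(in_epoch, rep(1L, 6))
  expect_equal(sum(in_epoch), length(locmax))
})

test_that("response amplitude is monotone in radiant exposure and zero at sham", {
  nr <- quiet_population()[1, ]
  qs <- c(0, 0.16, 0.29, 0.42, 0.5, 0.59, 0.68, 0.76)
  peaks <- vapply(qs, function(q) {
    f <- simulate_trial(nr, make_paradigm("multi_train", q), 30, seed = 1)
    max((f - nr$f0) / nr$f0)
  }, double(1))
  expect_equal(peaks[1], 0)
  expect_true(all(diff(peaks) >= 0))
})

test_that("raw traces stay strictly positive under default parameters", {
  cfg <- sim_config(n_excitatory = 4, n_inhibitory = 2,
    trials_per_intensity = 2, artifact_depth = 0.1)
  ds <- simulate_dataset(cfg, seed = 5)
  expect_true(all(is.finite(ds$f)))
  expect_true(all(ds$f > 0))
})

test_that("baseline dF/F0 averages to zero without spontaneous activity", {
  cfg <- sim_config(n_excitatory = 5, trials_per_intensity = 4,
    intensities = 0.76, spontaneous_rate = 0, noise_sigma = 0.05)
  ds <- simulate_dataset(cfg, seed = 9)
  avg <- average_responses(ds)
  base <- vapply(avg$dff, function(v) mean(v[1:300]), double(1))
  # Monte Carlo error of a mean of 300 x 4 noise samples
  expect_true(all(abs(base) < 5 * 0.05 / sqrt(300 * 4)))
})

test_that("dataset synthesis is seed-reproducible with randomised trial order", {
  cfg <- tiny_config()
  a <- simulate_dataset(cfg, seed = 21)
  b <- simulate_dataset(cfg, seed = 21)
  expect_identical(a$f, b$f)
  expect_identical(a$trials, b$trials)

  expect_equal(ncol(a$f),
    cfg$n_excitatory * length(cfg$intensities) * cfg$trials_per_intensity)
  expect_equal(nrow(a$f), 1800)
  # each intensity appears the configured number of times per neuron
  tab <- table(a$trials$intensity) / cfg$n_excitatory
  expect_true(all(tab == cfg$trials_per_intensity))

  one <- simulate_dataset(sim_config(n_excitatory = 1,
    trials_per_intensity = 1, intensities = 0.42), seed = 1)
  expect_equal(ncol(one$f), 1)

  expect_error(sim_config(intensities = numeric()), "non-empty")
})
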