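#' Difference-of-exponentials calcium impulse kernel
#'
#' Fast-rise, slow-decay kernel used for both stimulus-evoked and spontaneous
#' transients, normalised to unit peak. Zero for `t < 0`.
#'
#' @param t Time in seconds relative to event onset.
#' @param rise_s Rise time constant (s). Default 0.18.
#' @param decay_s Decay time constant (s). Default 1.5.
#' @return Numeric vector, same length as `t`, peak value 1.
#' @export
calcium_kernel <- function(t, rise_s = 0.18, decay_s = 1.5) {
  stopifnot(rise_s > 0, decay_s > rise_s)
  k <- ifelse(t < 0, 0, exp(-t / decay_s) - exp(-t / rise_s))
  # analytic peak of the difference of exponentials
  tpk <- log(decay_s / rise_s) / (1 / rise_s - 1 / decay_s)
  k / (exp(-tpk / decay_s) - exp(-tpk / rise_s))
}

#' Intensity-amplitude law
#'
#' Response amplitude as a function of per-pulse radiant exposure: linear
#' above a threshold, zero below, so amplitude is monotone non-decreasing in
#' intensity and exactly zero for a sham (0 J/cm^2) stimulus.
#'
#' @param radiant_exposure Radiant exposure Q in J/cm^2.
#' @param gain Slope in dF/F0 per J/cm^2 above threshold.
#' @param threshold Threshold radiant exposure (J/cm^2). Default 0.1.
#' @return Amplitude in dF/F0 units.
#' @export
amplitude_law <- function(radiant_exposure, gain, threshold = 0.1) {
  gain * pmax(0, radiant_exposure - threshold)
}

#' Sample a synthetic neuron population
#'
#' Draws neuron specifications for a mixed excitatory/inhibitory cohort.
#' Positions are uniform over the stated imaging field, the responsive flag
#' is drawn independently per neuron, and the output is deterministic given
#' the seed. Excitatory neurons respond with positive deflections
#' (`response_sign = +1`), inhibitory neurons with negative deflections
#' (`response_sign = -1`).
#'
#' @param n_excitatory,n_inhibitory Neuron counts (>= 0).
#' @param responsive_fraction Probability that a neuron is responsive.
#' @param field_um Length-3 field extent in micrometres (x, y, z).
#' @param seed Integer seed.
#' @param response_gain dF/F0 per J/cm^2 above threshold for responsive cells.
#' @param spontaneous_rate Spontaneous transient rate, events/s.
#' @param noise_sigma Additive Gaussian noise SD on dF/F0.
#' @param artifact_depth Fluoro-thermal dip depth (dF/F0 units at the top
#'   0.76 J/cm^2 intensity; scales linearly with intensity). Default 0.
#' @param f0 Baseline fluorescence (a.u.).
#' @return A tibble with one row per neuron: `neuron_id`, `cell_class`,
#'   `x_um`, `y_um`, `z_um`, `responsive`, `response_gain`, `response_sign`,
#'   `spontaneous_rate`, `noise_sigma`, `artifact_depth`, `f0`.
#' @export
sample_population <- function(n_excitatory, n_inhibitory,
                              responsive_fraction = 1,
                              field_um = c(400, 400, 100),
                              seed = 1L,
                              response_gain = 1,
                              spontaneous_rate = 0.05,
                              noise_sigma = 0.05,
                              artifact_depth = 0,
                              f0 = 100) {
  if (n_excitatory < 0 || n_inhibitory < 0)
    stop("neuron counts must be >= 0", call. = FALSE)
  stopifnot(responsive_fraction >= 0, responsive_fraction <= 1,
    length(field_um) == 3, noise_sigma >= 0, spontaneous_rate >= 0)
  n <- n_excitatory + n_inhibitory
  if (n == 0L) {
    return(tibble::tibble(neuron_id = integer(), cell_class = character(),
      x_um = double(), y_um = double(), z_um = double(),
      responsive = logical(), response_gain = double(),
      response_sign = double(), spontaneous_rate = double(),
      noise_sigma = double(), artifact_depth = double(), f0 = double()))
  }
  cls <- rep(c("excitatory", "inhibitory"), c(n_excitatory, n_inhibitory))
  with_seed(seed, {
    tibble::tibble(
      neuron_id = seq_len(n),
      cell_class = cls,
      x_um = stats::runif(n, 0, field_um[1]),
      y_um = stats::runif(n, 0, field_um[2]),
      z_um = stats::runif(n, 0, field_um[3]),
      responsive = stats::runif(n) < responsive_fraction,
      response_gain = response_gain,
      response_sign = ifelse(cls == "excitatory", 1, -1),
      spontaneous_rate = spontaneous_rate,
      noise_sigma = noise_sigma,
      artifact_depth = artifact_depth,
      f0 = f0)
  })
}

#' Simulate one raw fluorescence trace
#'
#' Generates a single-trial raw fluorescence trace for one neuron:
#' `F = F0 * (1 + dF/F0)` where the dF/F0 signal is the sum of
#' (i) one calcium transient per pulse train, `response_sign * A(Q)` scaled
#' copies of the calcium kernel convolved at train onsets, with `A(Q)` the
#' threshold-linear intensity-amplitude law; (ii) a fluoro-thermal artifact
#' dip, a boxcar of depth `artifact_depth * Q / 0.76` during each train;
#' (iii) spontaneous transients from a homogeneous Poisson event process; and
#' (iv) additive Gaussian noise. Deterministic given the seed.
#'
#' @param neuron One-row tibble (or named list) as returned by
#'   [sample_population()].
#' @param paradigm A `stim_paradigm`.
#' @param sampling_rate Imaging frame rate in Hz (default 30).
#' @param seed Integer seed.
#' @param amplitude_threshold Threshold of the intensity-amplitude law
#'   (J/cm^2).
#' @param kernel_rise_s,kernel_decay_s Calcium kernel time constants (s).
#' @param spont_amplitude Amplitude of spontaneous transients (dF/F0).
#' @return Numeric vector of raw fluorescence, length
#'   `round(trial_length * sampling_rate)`, with attribute `"dff_true"`
#'   holding the noiseless evoked dF/F0 component (ground truth).
#' @export
simulate_trial <- function(neuron, paradigm, sampling_rate = 30, seed = 1L,
                           amplitude_threshold = 0.1,
                           kernel_rise_s = 0.18, kernel_decay_s = 1.5,
                           spont_amplitude = 0.2) {
  stopifnot(sampling_rate > 0)
  nr <- as.list(neuron)
  n <- round(paradigm$trial_length_s * sampling_rate)
  t <- (seq_len(n) - 1L) / sampling_rate
  q <- paradigm$radiant_exposure

  amp <- if (isTRUE(nr$responsive))
    amplitude_law(q, nr$response_gain, amplitude_threshold) else 0
  evoked <- numeric(n)
  onsets <- train_onsets(paradigm)
  if (amp > 0) {
    for (on in onsets)
      evoked <- evoked + nr$response_sign * amp *
        calcium_kernel(t - on, kernel_rise_s, kernel_decay_s)
  }
  # fluoro-thermal dip: boxcar during each pulse train, linear in intensity,
  # depth parameterised at the top 0.76 J/cm^2 intensity
  if (nr$artifact_depth != 0 && q > 0) {
    depth <- nr$artifact_depth * q / 0.76
    for (on in onsets) {
      idx <- t >= on & t < on + paradigm$train_duration_s
      evoked[idx] <- evoked[idx] - depth
    }
  }

  dff <- evoked
  with_seed(seed, {
    if (nr$spontaneous_rate > 0) {
      n_ev <- stats::rpois(1, nr$spontaneous_rate * paradigm$trial_length_s)
      if (n_ev > 0) {
        ev_t <- stats::runif(n_ev, 0, paradigm$trial_length_s)
        for (et in ev_t)
          dff <- dff + spont_amplitude *
            calcium_kernel(t - et, kernel_rise_s, kernel_decay_s)
      }
    }
    if (nr$noise_sigma > 0)
      dff <- dff + stats::rnorm(n, 0, nr$noise_sigma)
  })

  f <- nr$f0 * (1 + dff)
  attr(f, "dff_true") <- evoked
  f
}

#' Synthetic dataset configuration
#'
#' Collects every knob of the generator with the study-condition defaults:
#' eight radiant exposures 0, 0.16, 0.29, 0.42, 0.50, 0.59, 0.68,
#' 0.76 J/cm^2, six trials per intensity, 30 Hz sampling, and the multi-train
#' paradigm.
#'
#' @param n_excitatory,n_inhibitory Cohort sizes.
#' @param responsive_fraction Fraction of responsive neurons.
#' @param intensities Radiant exposures (J/cm^2), one block of trials each.
#' @param trials_per_intensity Trials per intensity (default 6).
#' @param paradigm_kind `"multi_train"` or `"long_train"`.
#' @param sampling_rate Hz.
#' @param field_um Imaging field extent (x, y, z) in micrometres.
#' @param response_gain,spontaneous_rate,noise_sigma,artifact_depth,f0
#'   Passed to [sample_population()].
#' @param amplitude_threshold,kernel_rise_s,kernel_decay_s,spont_amplitude
#'   Passed to [simulate_trial()].
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_excitatory = 100, n_inhibitory = 0,
                       responsive_fraction = 1,
                       intensities = c(0, 0.16, 0.29, 0.42, 0.50, 0.59, 0.68, 0.76),
                       trials_per_intensity = 6,
                       paradigm_kind = "multi_train",
                       sampling_rate = 30,
                       field_um = c(400, 400, 100),
                       response_gain = 1,
                       spontaneous_rate = 0.05,
                       noise_sigma = 0.05,
                       artifact_depth = 0,
                       f0 = 100,
                       amplitude_threshold = 0.1,
                       kernel_rise_s = 0.18, kernel_decay_s = 1.5,
                       spont_amplitude = 0.2) {
  cfg <- as.list(environment())
  if (length(cfg$intensities) == 0)
    stop("intensity list must be non-empty", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a full synthetic INS dataset
#'
#' Samples a neuron population, randomises the trial order over intensities
#' (laser powers presented in randomised order within a session), and
#' simulates every neuron on every trial. Ground-truth neuron specifications
#' are retained alongside the traces for recovery testing. Identical config
#' and seed give bit-identical datasets.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; all randomness (population, trial order,
#'   per-trace noise) is derived from it via sampled sub-seeds.
#' @return An `ins_dataset`: list with elements `f` (samples x traces raw
#'   fluorescence matrix), `trials` (tibble: `trace_id`, `trial`,
#'   `neuron_id`, `intensity`), `neurons` (ground-truth tibble), `paradigm`,
#'   `sampling_rate`, `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$intensities) == 0)
    stop("intensity list must be non-empty", call. = FALSE)

  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  neurons <- sample_population(config$n_excitatory, config$n_inhibitory,
    config$responsive_fraction, config$field_um, seed = sub[1],
    response_gain = config$response_gain,
    spontaneous_rate = config$spontaneous_rate,
    noise_sigma = config$noise_sigma,
    artifact_depth = config$artifact_depth, f0 = config$f0)

  trial_int <- rep(config$intensities, each = config$trials_per_intensity)
  n_trials <- length(trial_int)
  trial_int <- with_seed(sub[2], sample(trial_int))

  n_neurons <- nrow(neurons)
  n_traces <- n_neurons * n_trials
  paradigm0 <- make_paradigm(config$paradigm_kind, 0)
  n_samples <- round(paradigm0$trial_length_s * config$sampling_rate)

  trials <- tibble::tibble(
    trace_id = seq_len(n_traces),
    trial = rep(seq_len(n_trials), times = n_neurons),
    neuron_id = rep(neurons$neuron_id, each = n_trials),
    intensity = rep(trial_int, times = n_neurons))

  trace_seeds <- with_seed(seed + 1L,
    sample.int(.Machine$integer.max - 1L, max(n_traces, 1L)))

  f <- matrix(NA_real_, n_samples, n_traces)
  paradigms <- lapply(config$intensities,
    function(q) make_paradigm(config$paradigm_kind, q))
  names(paradigms) <- as.character(config$intensities)
  nr_rows <- lapply(seq_len(n_neurons), function(i) as.list(neurons[i, ]))
  names(nr_rows) <- as.character(neurons$neuron_id)
  for (k in seq_len(n_traces)) {
    nr <- nr_rows[[as.character(trials$neuron_id[k])]]
    par_k <- paradigms[[as.character(trials$intensity[k])]]
    f[, k] <- simulate_trial(nr, par_k, config$sampling_rate,
      seed = trace_seeds[k],
      amplitude_threshold = config$amplitude_threshold,
      kernel_rise_s = config$kernel_rise_s,
      kernel_decay_s = config$kernel_decay_s,
      spont_amplitude = config$spont_amplitude)
  }

  structure(list(f = f, trials = trials, neurons = neurons,
    paradigm = paradigm0, sampling_rate = config$sampling_rate,
    config = config, seed = seed), class = "ins_dataset")
}

#' @export
print.ins_dataset <- function(x, ...) {
  cat(sprintf(
    "<ins_dataset: %d neurons x %d trials (%d traces of %d samples at %g Hz)>\n",
    nrow(x$neurons), length(unique(x$trials$trial)), ncol(x$f), nrow(x$f),
    x$sampling_rate))
  cat("  paradigm:", x$paradigm$label,
    "| intensities:", paste(sort(unique(x$trials$intensity)), collapse = ", "),
    "J/cm2\n")
  invisible(x)
}

#' Flatten an INS dataset to a long tibble
#'
#' One row per sample: `neuron_id`, `trial`, `intensity`, `time_s`, `f`.
#'
#' @param x An `ins_dataset`.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom tibble as_tibble
#' @export
as_tibble.ins_dataset <- function(x, ...) {
  n_samples <- nrow(x$f)
  t <- (seq_len(n_samples) - 1L) / x$sampling_rate
  tibble::tibble(
    neuron_id = rep(x$trials$neuron_id, each = n_samples),
    trial = rep(x$trials$trial, each = n_samples),
    intensity = rep(x$trials$intensity, each = n_samples),
    time_s = rep(t, times = ncol(x$f)),
    f = as.vector(x$f))
}

# run expr with a temporary RNG state seeded at `seed`; restores the caller's
# RNG so dataset generation does not perturb unrelated randomness
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
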