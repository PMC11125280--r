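#' Construct an INS stimulation paradigm
#'
#' Builds the full temporal description of one infrared neural stimulation
#' (INS) trial. Two paradigms are supported:
#'
#' * `"multi_train"`: a 60 s trial with a 10 s baseline followed by an 18 s
#'   stimulation epoch containing six 0.5 s pulse trains (0.25 ms pulses at
#'   200 Hz, 100 pulses per train) separated by 2.5 s intervals, then a 32 s
#'   recovery period.
#' * `"long_train"`: a 30 s trial with a 3 s baseline, a single 2 s pulse
#'   train (400 pulses at 200 Hz) and a 25 s recovery period.
#'
#' All times are in seconds from trial start and intervals are half-open
#' `[start, end)`.
#'
#' @param kind Paradigm label, `"multi_train"` or `"long_train"`.
#' @param radiant_exposure Per-pulse radiant exposure at the fiber tip in
#'   J/cm^2. Zero is a valid sham stimulus.
#' @param pulse_width_ms Pulse width in milliseconds.
#' @param pulse_rate_hz Pulse repetition rate within a train, in Hz.
#' @return A `stim_paradigm` object: a list with fields `pulse_width_ms`,
#'   `pulse_rate_hz`, `train_duration_s`, `n_trains`, `train_interval_s`,
#'   `trial_length_s`, `baseline_length_s`, `radiant_exposure` and `label`.
#' @examples
#' p <- make_paradigm("multi_train", 0.42)
#' pulses_per_train(p) # 100
#' train_onsets(p)     # 10, 13, 16, 19, 22, 25
#' @export
make_paradigm <- function(kind = c("multi_train", "long_train"),
                          radiant_exposure = 0.42,
                          pulse_width_ms = 0.25,
                          pulse_rate_hz = 200) {
  kind <- tryCatch(match.arg(kind),
    error = function(e) stop("unknown paradigm kind: ", paste(kind, collapse = ", "),
      call. = FALSE))
  stopifnot(is.numeric(radiant_exposure), length(radiant_exposure) == 1L)
  if (radiant_exposure < 0) stop("radiant_exposure must be >= 0", call. = FALSE)

  p <- switch(kind,
    multi_train = list(
      pulse_width_ms = pulse_width_ms, pulse_rate_hz = pulse_rate_hz,
      train_duration_s = 0.5, n_trains = 6L, train_interval_s = 2.5,
      trial_length_s = 60, baseline_length_s = 10,
      radiant_exposure = radiant_exposure, label = "multi_train"),
    long_train = list(
      pulse_width_ms = pulse_width_ms, pulse_rate_hz = pulse_rate_hz,
      train_duration_s = 2, n_trains = 1L, train_interval_s = 0,
      trial_length_s = 30, baseline_length_s = 3,
      radiant_exposure = radiant_exposure, label = "long_train"))
  class(p) <- "stim_paradigm"
  validate_paradigm(p)
  p
}

validate_paradigm <- function(p) {
  ppt <- p$pulse_rate_hz * p$train_duration_s
  if (ppt <= 0 || abs(ppt - round(ppt)) > 1e-9)
    stop("pulses per train (pulse_rate * train_duration) must be a positive integer",
      call. = FALSE)
  stim <- stim_epoch_length(p)
  if (p$baseline_length_s + stim > p$trial_length_s)
    stop("baseline + stimulation epoch exceed trial length", call. = FALSE)
  invisible(p)
}

stim_epoch_length <- function(p) {
  p$n_trains * (p$train_duration_s + p$train_interval_s)
}

#' Number of laser pulses in one train
#' @param paradigm A `stim_paradigm`.
#' @return Integer pulse count (rate x duration).
#' @export
pulses_per_train <- function(paradigm) {
  as.integer(round(paradigm$pulse_rate_hz * paradigm$train_duration_s))
}

#' Pulse-train onset times
#'
#' Train i starts at `baseline + (i - 1) * (train_duration + train_interval)`;
#' for the multi-train paradigm this partitions the 18 s stimulation epoch
#' into six equal 3 s train epochs starting at 10, 13, ..., 25 s.
#'
#' @param paradigm A `stim_paradigm`.
#' @return Numeric vector of onset times in seconds.
#' @export
train_onsets <- function(paradigm) {
  paradigm$baseline_length_s +
    (seq_len(paradigm$n_trains) - 1L) *
      (paradigm$train_duration_s + paradigm$train_interval_s)
}

#' Stimulation analysis window
#'
#' The half-open interval `[baseline, baseline + stimulation epoch)` covering
#' all pulse trains and inter-train intervals: 10--28 s for the multi-train
#' paradigm, 3--5 s for the long-train paradigm.
#'
#' @param paradigm A `stim_paradigm`.
#' @return Length-2 numeric `c(start, end)` in seconds.
#' @export
stim_window <- function(paradigm) {
  c(paradigm$baseline_length_s,
    paradigm$baseline_length_s + stim_epoch_length(paradigm))
}

#' Baseline window of a paradigm
#' @param paradigm A `stim_paradigm`.
#' @return `c(0, baseline_length)` in seconds.
#' @export
baseline_window <- function(paradigm) {
  c(0, paradigm$baseline_length_s)
}

#' @export
print.stim_paradigm <- function(x, ...) {
  cat(sprintf(
    "<stim_paradigm: %s>\n  %d train(s) x %.2g s at %g Hz (%d pulses/train), interval %.2g s\n  trial %g s, baseline %g s, radiant exposure %g J/cm2/pulse\n",
    x$label, x$n_trains, x$train_duration_s, x$pulse_rate_hz,
    pulses_per_train(x), x$train_interval_s, x$trial_length_s,
    x$baseline_length_s, x$radiant_exposure))
  invisible(x)
}

# sample indices whose time (k-1)/fs falls in half-open [w1, w2)
window_indices <- function(window, sampling_rate, n_samples) {
  t <- (seq_len(n_samples) - 1L) / sampling_rate
  which(t >= window[1] & t < window[2])
}
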